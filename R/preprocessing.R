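# Gross-error rejection, smoothing and checkpoint completion for WBIA series.

#' Romanovsky critical coefficient
#'
#' The gross-error criterion tests the most suspicious sample against the
#' mean and standard deviation of the *remaining* n-1 samples (the deleted
#' estimate with n-2 degrees of freedom).  Under the null, the deleted
#' deviation divided by the deleted SD follows \eqn{t_{n-2}} after a
#' \eqn{\sqrt{n/(n-1)}} variance correction, so the exact critical
#' coefficient is \deqn{K(n, \alpha) = t_{1-\alpha/2,\,n-2}\,\sqrt{n/(n-1)}.}
#'
#' @param n Series length including the suspect (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @param correction `"max"` (default) adjusts for testing the most extreme
#'   of n candidates (Bonferroni, level alpha/n per suspect), the
#'   appropriate level for an iterated maximum-deviate test; `"pointwise"`
#'   applies alpha per suspect unadjusted.
#' @return The critical coefficient K such that a suspect is rejected when
#'   its absolute deleted deviation exceeds K times the deleted SD.
#' @export
romanovsky_k <- function(n, alpha = 0.05,
                         correction = c("max", "pointwise")) {
  correction <- match.arg(correction)
  stopifnot(n >= 4, alpha > 0, alpha < 1)
  a <- if (correction == "max") alpha / n else alpha
  qt(1 - a / 2, df = n - 2) * sqrt(n / (n - 1))
}

#' Iterative gross-error removal by the Romanovsky criterion
#'
#' At each iteration the sample with the largest absolute deviation from the
#' leave-one-out mean is tested: with \eqn{x_p} and \eqn{\sigma} computed
#' from the other samples (denominator n-2), the suspect is removed when
#' \eqn{|x_i - x_p| > K\sigma}.  Iteration stops when no sample exceeds the
#' bound, when fewer than 4 samples remain, or after `max_iterations`
#' removals.  The filter is idempotent: re-filtering a cleaned series removes
#' nothing.
#'
#' @param series Numeric vector, length >= 4.
#' @param alpha Two-sided significance level (default 0.05).
#' @param max_iterations Maximum removals (default the series length).
#' @param correction Passed to [romanovsky_k()]; the default `"max"`
#'   accounts for the suspect being the most extreme of n candidates.
#' @return A list with `cleaned` (the retained values, original order) and
#'   `removed_indices` (integer positions in the original series, possibly
#'   empty).
#' @export
romanovsky_filter <- function(series, alpha = 0.05,
                              max_iterations = length(series),
                              correction = c("max", "pointwise")) {
  correction <- match.arg(correction)
  if (length(series) < 4) {
    stop("insufficient data: romanovsky_filter needs at least 4 samples", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  keep <- seq_along(series)
  removed <- integer()
  for (iter in seq_len(max_iterations)) {
    x <- series[keep]
    n <- length(x)
    if (n < 4) break
    s_tot <- sum(x)
    ss_tot <- sum(x^2)
    xp <- (s_tot - x) / (n - 1)                     # leave-one-out means
    # leave-one-out sum of squared deviations about xp:
    # sum_{i != j} (x_i - xp_j)^2 = (ss_tot - x_j^2) - (n-1) xp_j^2
    sigma2 <- pmax((ss_tot - x^2 - (n - 1) * xp^2) / (n - 2), 0)
    dev <- abs(x - xp)
    j <- which.max(dev)
    sig <- sqrt(sigma2[j])
    k <- romanovsky_k(n, alpha, correction)
    exceeds <- if (sig == 0) dev[j] > 0 else dev[j] > k * sig
    if (!exceeds) break
    removed <- c(removed, keep[j])
    keep <- keep[-j]
  }
  list(cleaned = series[sort(keep)], removed_indices = sort(removed))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with a symmetric window of
#' half-width `w` (window length 2w+1) and polynomial order `poly_order`.
#' Interior points are the classical convolution with the least-squares
#' coefficients; edge points use the polynomial fit of the first/last full
#' window evaluated at the edge positions, so any input that is globally a
#' polynomial of degree at most `poly_order` is reproduced exactly.
#'
#' @param series Numeric vector, length >= 2w+1.
#' @param w Window half-width (default 5, an 11-point window).
#' @param poly_order Polynomial order (default 3); must be < 2w+1.
#' @return Smoothed numeric vector, same length as the input.
#' @export
savgol_smooth <- function(series, w = 5, poly_order = 3) {
  stopifnot(w >= 1, poly_order >= 0, poly_order < 2 * w + 1)
  if (length(series) < 2 * w + 1) {
    stop("window longer than series: need length >= ", 2 * w + 1, call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(series, p = poly_order, n = 2 * w + 1))
}

#' Interior Savitzky-Golay convolution coefficients
#'
#' The centre-point least-squares weights \eqn{h_i / H} for a window of
#' half-width `w` and the given polynomial order, e.g. (-3, 12, 17, 12, -3)/35
#' for w = 2, order 2.
#'
#' @inheritParams savgol_smooth
#' @return Numeric vector of length 2w+1 summing to 1.
#' @export
savgol_coefficients <- function(w, poly_order) {
  stopifnot(w >= 1, poly_order >= 0, poly_order < 2 * w + 1)
  m <- signal::sgolay(p = poly_order, n = 2 * w + 1)
  as.numeric(m[w + 1, ])
}

#' Natural cubic-spline completion of sparse checkpoints
#'
#' Interpolates a sparse checkpoint series onto a dense query grid with a
#' natural cubic spline (zero second derivative at the end knots): exact at
#' the knots and C2 in the interior.  No extrapolation is performed.
#'
#' @param time_h Strictly increasing checkpoint times (>= 3).
#' @param value Checkpoint values.
#' @param query_times Query times, all within `[min(time_h), max(time_h)]`.
#' @return Interpolated values at `query_times`.
#' @export
spline_complete <- function(time_h, value, query_times) {
  stopifnot(length(time_h) == length(value))
  if (length(time_h) < 3) {
    stop("spline completion needs at least 3 checkpoints", call. = FALSE)
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("checkpoint times must be strictly increasing", call. = FALSE)
  }
  if (any(query_times < min(time_h) - 1e-12) || any(query_times > max(time_h) + 1e-12)) {
    stop("extrapolation error: query times outside the checkpoint range", call. = FALSE)
  }
  spline(time_h, value, xout = query_times, method = "natural")$y
}

#' Complete a stress series onto a dense time grid
#'
#' Applies [spline_complete()] per stress factor.
#'
#' @param stress A [stress_series()] of sparse checkpoints.
#' @param query_times Dense time grid within the checkpoint range.
#' @return A [stress_series()] on `query_times`.
#' @export
complete_stress_series <- function(stress, query_times) {
  stopifnot(inherits(stress, "stress_series"))
  vals <- lapply(STRESS_FACTORS, function(f) {
    spline_complete(stress$time_h, stress[[f]], query_times)
  })
  names(vals) <- STRESS_FACTORS
  stress_series(query_times, vals$glucose, vals$lactate, vals$cortisol,
                units = attr(stress, "units"))
}

#' Preprocess sweep frames: gross-error removal then smoothing
#'
#' For each frequency and each raw channel (`r_ohm`, `i_ohm`) independently:
#' the channel is first detrended with a running median (stress drives a
#' slow monotone drift that would otherwise swamp the gross-error test);
#' samples flagged by the Romanovsky criterion on the detrended residuals
#' are replaced by linear interpolation of their neighbours (the time grid
#' must stay complete for the downstream sliding windows); the channel is
#' then Savitzky-Golay smoothed.  Magnitude and phase are recomputed from
#' the cleaned channels.
#'
#' @param frames A [sweep_frames()] table.
#' @param alpha Romanovsky significance level (default 0.05).
#' @param w,poly_order Savitzky-Golay window half-width and order.
#' @param detrend_width Odd running-median width for detrending before the
#'   gross-error test (default 9 samples).
#' @return A list with `frames` (cleaned `sweep_frames`) and `removed`
#'   (data.frame `timestamp`, `frequency_khz`, `channel`, `original_value`).
#' @export
preprocess_sweeps <- function(frames, alpha = 0.05, w = 5, poly_order = 3,
                              detrend_width = 9) {
  stopifnot(inherits(frames, "sweep_frames"))
  freqs <- sort(unique(frames$frequency_khz))
  removed_log <- list()
  out <- frames
  for (f in freqs) {
    sel <- which(frames$frequency_khz == f)
    sel <- sel[order(frames$timestamp[sel])]
    for (channel in c("r_ohm", "i_ohm")) {
      x <- frames[[channel]][sel]
      trend <- if (length(x) >= detrend_width) {
        stats::runmed(x, detrend_width, endrule = "median")
      } else rep(stats::median(x), length(x))
      flt <- romanovsky_filter(x - trend, alpha = alpha)
      if (length(flt$removed_indices)) {
        removed_log[[length(removed_log) + 1L]] <- data.frame(
          timestamp = frames$timestamp[sel][flt$removed_indices],
          frequency_khz = f, channel = channel,
          original_value = x[flt$removed_indices])
        good <- setdiff(seq_along(x), flt$removed_indices)
        x[flt$removed_indices] <- approx_fill(seq_along(x), x, good,
                                              flt$removed_indices)
      }
      if (length(x) >= 2 * w + 1) x <- savgol_smooth(x, w = w, poly_order = poly_order)
      out[[channel]][sel] <- x
    }
  }
  mp <- magnitude_phase(out$r_ohm, out$i_ohm)
  out$magnitude <- mp$magnitude
  out$phase_rad <- mp$phase_rad
  removed <- if (length(removed_log)) do.call(rbind, removed_log) else
    data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
               frequency_khz = numeric(), channel = character(),
               original_value = numeric())
  list(frames = out, removed = removed)
}

# Linear interpolation of flagged positions from retained neighbours,
# constant extension at the ends.
approx_fill <- function(idx, x, good, bad) {
  stats::approx(idx[good], x[good], xout = idx[bad], rule = 2)$y
}
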
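# Grey relational stress-weight allocation and MIC-based feature screening.

#' Grey relational coefficients
#'
#' Per-time-point relational coefficients between a reference series
#' \eqn{x_0} and a comparison series \eqn{x_i}:
#' \deqn{\zeta(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta(k) + \rho\,\Delta_{max}}}
#' with \eqn{\Delta(k) = |x_0(k) - x_i(k)|} and extrema taken over the whole
#' call context.  When several comparison series share one reference (as in
#' [allocate_stress_weights()]) the extrema are joint over all of them; pass
#' them via `delta_min`/`delta_max`.  Both series are expected min-max
#' normalized to [0, 1] beforehand.
#'
#' @param reference,comparison Equal-length numeric vectors (length >= 2).
#' @param rho Resolution coefficient in (0, 1); smaller values spread the
#'   coefficients further apart.  Default 0.5.
#' @param delta_min,delta_max Optional context extrema of
#'   \eqn{|x_0 - x_i|}; computed from this pair when omitted.
#' @return Numeric vector of coefficients, each in (0, 1].
#' @export
gra_coefficients <- function(reference, comparison, rho = 0.5,
                             delta_min = NULL, delta_max = NULL) {
  if (length(reference) != length(comparison)) {
    stop("gra_coefficients: reference and comparison lengths differ", call. = FALSE)
  }
  stopifnot(length(reference) >= 2, rho > 0, rho < 1)
  delta <- abs(reference - comparison)
  if (is.null(delta_min)) delta_min <- min(delta)
  if (is.null(delta_max)) delta_max <- max(delta)
  if (delta_max == 0) return(rep(1, length(delta)))  # identical series
  (delta_min + rho * delta_max) / (delta + rho * delta_max)
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))  # constant series: centred
  (x - r[1]) / (r[2] - r[1])
}

#' Allocate stress-factor weights by grey relational analysis
#'
#' Each nutrient series (min-max normalized) acts as a reference, each
#' stress factor as a comparison; the relational grade of a factor is the
#' mean coefficient over time and over all nutrient references, and the
#' weights are the grades normalized to sum to 1.  Extrema
#' \eqn{\Delta_{min}, \Delta_{max}} are joint over the comparison series
#' within each reference.
#'
#' @param stress A [stress_series()].
#' @param nutrients A [nutrient_panel()]; both are matched on common
#'   checkpoint times (>= 2 required).
#' @param rho Resolution coefficient (default 0.5).
#' @return An object of class `weight_vector`: list with `weights` (named,
#'   summing to 1) and `relational_grades`.
#' @export
allocate_stress_weights <- function(stress, nutrients, rho = 0.5) {
  stopifnot(inherits(stress, "stress_series"), inherits(nutrients, "nutrient_panel"))
  common <- intersect(stress$time_h, nutrients$time_h)
  if (length(common) < 2) {
    stop("allocate_stress_weights: fewer than 2 common time points", call. = FALSE)
  }
  s_idx <- match(common, stress$time_h)
  n_idx <- match(common, nutrients$time_h)
  s_norm <- lapply(STRESS_FACTORS, function(f) minmax_scale(stress[[f]][s_idx]))
  names(s_norm) <- STRESS_FACTORS
  n_norm <- lapply(NUTRIENTS, function(nm) minmax_scale(nutrients[[nm]][n_idx]))
  names(n_norm) <- NUTRIENTS

  grade_mat <- sapply(STRESS_FACTORS, function(f) {
    vapply(NUTRIENTS, function(nm) {
      deltas <- lapply(STRESS_FACTORS, function(g) abs(n_norm[[nm]] - s_norm[[g]]))
      dmin <- min(unlist(deltas))
      dmax <- max(unlist(deltas))
      mean(gra_coefficients(n_norm[[nm]], s_norm[[f]], rho,
                            delta_min = dmin, delta_max = dmax))
    }, numeric(1))
  })
  grades <- colMeans(grade_mat)
  weight_vector(grades / sum(grades), relational_grades = grades)
}

#' Construct a weight vector
#'
#' @param weights Named nonnegative weights over the stress factors; must sum
#'   to 1 within 1e-9 (a single factor is normalized automatically).
#' @param relational_grades Optional named grades in (0, 1].
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights, relational_grades = NULL) {
  stopifnot(is.numeric(weights), !is.null(names(weights)), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weight_vector: weights must sum to 1", call. = FALSE)
  }
  structure(list(weights = weights, relational_grades = relational_grades),
            class = "weight_vector")
}

#' Reference stress weights from the turbot monitoring study
#'
#' The fixed fallback weight allocation used when no nutrient data are
#' available to recompute GRA weights: lactate 0.396, glucose 0.290,
#' cortisol 0.314.
#'
#' @return A `weight_vector`.
#' @export
default_stress_weights <- function() {
  weight_vector(c(glucose = 0.290, lactate = 0.396, cortisol = 0.314))
}

#' Maximal information coefficient
#'
#' \deqn{MIC(x; y) = \max_{cr \le B} \frac{I(X; Y)}{\log_2 \min(c, r)}}
#' over grid partitions of the scatterplot into c columns and r rows.  For a
#' fixed row partition the optimal column partition of each size is found
#' exactly by dynamic programming.  At small n (<= 14) every row partition
#' is enumerated, making the search exhaustive; at larger n rows are
#' rank-equipartitions of sizes 2..B/2 in both orientations (the standard
#' approximation).
#'
#' @param x,y Equal-length numeric vectors, n >= 8, neither constant.
#' @param b_rule Grid-size budget: `"FACTOR_0_6"` (B = 0.6 n, the monitoring
#'   study's stated rule, sensible at checkpoint-scale n) or `"POWER_0_6"`
#'   (B = n^0.6, the standard MINE convention, preferred for n in the
#'   hundreds).  See the methods vignette for why the two regimes differ.
#' @return MIC in [0, 1].
#' @export
mic <- function(x, y, b_rule = c("FACTOR_0_6", "POWER_0_6")) {
  b_rule <- match.arg(b_rule)
  if (length(x) != length(y)) stop("mic: x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 8) stop("mic: need at least 8 samples", call. = FALSE)
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("undefined MIC: constant input series", call. = FALSE)
  }
  B <- if (b_rule == "FACTOR_0_6") floor(0.6 * n) else floor(n^0.6)
  B <- max(B, 4)
  if (n <= 14) mic_exact(x, y, B) else mic_heuristic(x, y, B)
}

# Cut allowed between sorted neighbours only where the value changes.
cuts_allowed <- function(sorted_vals) diff(sorted_vals) != 0

# Exact search: enumerate every row partition of one axis (all subsets of
# allowed gaps with r parts), exact DP on the other.  Covers all grids.
mic_exact <- function(x, y, B) {
  ord_x <- order(x, y)
  y_by_x <- y[ord_x]
  cut_x <- cuts_allowed(x[ord_x])
  ys <- sort(unique(y))
  gap_vals <- ys[-length(ys)]          # cut after each distinct value
  best <- 0
  r_max <- min(floor(B / 2), length(ys))
  for (r in 2:r_max) {
    if (length(gap_vals) < r - 1) break
    combs <- utils::combn(length(gap_vals), r - 1, simplify = FALSE)
    cmax <- floor(B / r)
    for (cb in combs) {
      breaks <- gap_vals[cb]
      # cut AFTER each break value: points equal to it belong to the lower bin
      ybin <- findInterval(y_by_x, breaks, left.open = TRUE) + 1L
      ii <- mic_dp(as.integer(ybin), r, cmax, cut_x)
      for (l in 2:cmax) {
        v <- ii[l] / log2(min(l, r))
        if (v > best) best <- v
      }
    }
  }
  min(max(best, 0), 1)
}

# Rank-equipartition rows (both orientations) + exact DP columns.
mic_heuristic <- function(x, y, B) {
  best <- 0
  for (swap in c(FALSE, TRUE)) {
    a <- if (swap) y else x   # column axis (DP)
    b <- if (swap) x else y   # row axis (equipartition)
    ord <- order(a, b)
    b_by_a <- b[ord]
    cut_a <- cuts_allowed(a[ord])
    n <- length(a)
    for (r in 2:floor(B / 2)) {
      qs <- unique(quantile(b, probs = seq_len(r - 1) / r, type = 1, names = FALSE))
      # left-open binning keeps each quantile value in the lower row, giving
      # balanced rank-equipartitions (exactly n/r per row when r divides n)
      ybin <- findInterval(b_by_a, qs, left.open = TRUE) + 1L
      r_eff <- length(unique(ybin))
      if (r_eff < 2) next
      cmax <- floor(B / r)
      ii <- mic_dp(as.integer(ybin), max(ybin), cmax, cut_a)
      for (l in 2:cmax) {
        v <- ii[l] / log2(min(l, r_eff))
        if (v > best) best <- v
      }
    }
  }
  min(max(best, 0), 1)
}

#' WBIA feature matrix from sweep frames
#'
#' One column per (channel, frequency): calibrated impedance magnitude and
#' phase at each sweep frequency, labelled `impedance_<f>` / `phase_<f>`,
#' over the common time grid, plus `temperature`.
#'
#' @param frames A [sweep_frames()] table.
#' @param include_temperature Append the temperature column (default TRUE).
#' @return Numeric matrix, rows = timestamps (sorted), with an attribute
#'   `time_h` of hours since the first timestamp.
#' @export
wbia_feature_matrix <- function(frames, include_temperature = TRUE) {
  stopifnot(inherits(frames, "sweep_frames"))
  freqs <- sort(unique(frames$frequency_khz))
  times <- sort(unique(frames$timestamp))
  n_t <- length(times)
  cols <- list()
  for (f in freqs) {
    sub <- frames[frames$frequency_khz == f, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    stopifnot(nrow(sub) == n_t)
    cols[[paste0("impedance_", f)]] <- sub$magnitude
    cols[[paste0("phase_", f)]] <- sub$phase_rad
  }
  if (include_temperature) {
    sub <- frames[frames$frequency_khz == freqs[1], , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    cols$temperature <- sub$temperature_c
  }
  m <- do.call(cbind, cols)
  # order columns channel-major: impedance_30..impedance_100, phase_30.., temp
  lab <- c(paste0("impedance_", freqs), paste0("phase_", freqs),
           if (include_temperature) "temperature")
  m <- m[, lab, drop = FALSE]
  attr(m, "time_h") <- as.numeric(difftime(times, times[1], units = "hours"))
  m
}

#' MIC matrix between WBIA features and stress factors
#'
#' @param features Numeric matrix of WBIA features (columns labelled), e.g.
#'   from [wbia_feature_matrix()]; the `temperature` column is excluded.
#' @param stress A [stress_series()] on the same time grid (same row count).
#' @param b_rule Passed to [mic()].
#' @return Matrix of MIC values, rows = feature labels, cols = stress
#'   factors, with attribute `b_rule`.
#' @export
mic_matrix <- function(features, stress, b_rule = c("FACTOR_0_6", "POWER_0_6")) {
  b_rule <- match.arg(b_rule)
  stopifnot(inherits(stress, "stress_series"), nrow(features) == nrow(stress))
  labs <- setdiff(colnames(features), "temperature")
  m <- matrix(NA_real_, length(labs), length(STRESS_FACTORS),
              dimnames = list(labs, STRESS_FACTORS))
  for (lab in labs) {
    for (f in STRESS_FACTORS) {
      m[lab, f] <- mic(features[, lab], stress[[f]], b_rule = b_rule)
    }
  }
  attr(m, "b_rule") <- b_rule
  m
}

#' Screen WBIA features by MIC threshold
#'
#' A feature is selected when its MIC against the stress factors meets the
#' threshold; with `rule = "all"` (default, matching the monitoring study's
#' screening, where every selected row passed for all three factors) the
#' condition must hold for every factor, with `rule = "any"` for at least
#' one.  Selection preserves the (channel, frequency) row order.
#'
#' @param mic_mat Matrix from [mic_matrix()] (or any numeric matrix with
#'   feature rownames and factor columns).
#' @param threshold MIC threshold in [0, 1] (default 0.9).
#' @param rule `"all"` or `"any"`.
#' @return Character vector of selected feature labels.
#' @export
screen_features <- function(mic_mat, threshold = 0.9, rule = c("all", "any")) {
  rule <- match.arg(rule)
  if (is.null(dim(mic_mat)) || nrow(mic_mat) == 0) {
    stop("screen_features: empty MIC matrix", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  hit <- mic_mat >= threshold
  sel <- if (rule == "all") apply(hit, 1, all) else apply(hit, 1, any)
  rownames(mic_mat)[sel]
}
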
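# Nutrient health score, weighted total stress, Z-shaped fuzzy membership
# and the five-level health classification (SLL/MLL/BLL/WLL/DS).

HEALTH_LEVELS <- c("SLL", "MLL", "BLL", "WLL", "DS")

#' Zone-specific health classification thresholds
#'
#' The published criteria for medium-sized fish: ZMF adjustment coefficients
#' (`a`, `b`) and the average-total-stress breakpoints separating the five
#' levels (left-closed, right-open intervals on the stress axis), plus the
#' companion health-score breakpoints.  These breakpoints are configuration
#' constants of the classification scheme, not recomputed quantities.
#'
#' @param zone `"ZONE_1_3"` (1-3 degrees C) or `"ZONE_3_6"` (3-6 degrees C).
#' @return A list with `a`, `b`, `stress_breaks` (length 4, increasing) and
#'   `score_breaks`.
#' @export
level_thresholds <- function(zone = c("ZONE_1_3", "ZONE_3_6")) {
  zone <- match.arg(zone)
  if (zone == "ZONE_1_3") {
    list(zone = zone, a = 0.019, b = 1,
         stress_breaks = c(0.406, 0.625, 0.783, 0.792),
         score_breaks = c(0.857, 0.429, 0.143, 0.131))
  } else {
    list(zone = zone, a = 0.0138, b = 1,
         stress_breaks = c(0.368, 0.597, 0.767, 0.779),
         score_breaks = c(0.857, 0.429, 0.143, 0.131))
  }
}

#' Nutrient-based health score
#'
#' Every nutrient series is min-max normalized so that it equals 1 at time 0
#' (series that rise over the run, such as muscle lactate, are
#' orientation-flipped first); the health score at a time point is the mean
#' normalized value over the H nutrients.  A fresh fish scores 1; a fully
#' depleted fish scores 0.
#'
#' @param panel A [nutrient_panel()].
#' @param at_time Time (hours) at which to score; must lie on the panel grid.
#' @return Health score in [0, 1].
#' @export
health_score <- function(panel, at_time) {
  stopifnot(inherits(panel, "nutrient_panel"))
  if (nrow(panel) == 0) stop("health_score: empty panel", call. = FALSE)
  j <- match(at_time, panel$time_h)
  if (is.na(j)) {
    if (at_time < min(panel$time_h) || at_time > max(panel$time_h)) {
      stop("health_score: time outside the panel range", call. = FALSE)
    }
    j <- which.min(abs(panel$time_h - at_time))
  }
  norm_vals <- vapply(NUTRIENTS, function(nm) {
    x <- panel[[nm]]
    r <- range(x)
    if (r[1] == r[2]) return(1)
    v <- (x - r[1]) / (r[2] - r[1])
    if (v[1] < v[length(v)]) v <- 1 - v   # rising series: flip so t0 ~ 1
    v[j]
  }, numeric(1))
  mean(norm_vals)
}

#' Weighted total stress
#'
#' \deqn{S_{total}(t) = \sum_i W_i \, \mathrm{norm}\,S_i(t)} with min-max
#' normalization of each factor by the supplied bounds; weights must sum to
#' 1, so the result lies in [0, 1].
#'
#' @param stress_at_t Named per-factor values (glucose, lactate, cortisol).
#' @param weights A [weight_vector()].
#' @param normalizers Named list of `c(min, max)` bounds per factor; pass
#'   `NULL` bounds-free values already normalized to [0, 1].
#' @return Total stress in [0, 1].
#' @export
total_stress <- function(stress_at_t, weights, normalizers = NULL) {
  stopifnot(inherits(weights, "weight_vector"))
  w <- weights$weights
  missing_w <- setdiff(names(stress_at_t), names(w))
  if (length(missing_w)) {
    stop("total_stress: no weight for factor(s) ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(names(w), function(f) {
    v <- stress_at_t[[f]]
    if (is.null(v)) stop("total_stress: factor '", f, "' missing", call. = FALSE)
    if (!is.null(normalizers)) {
      b <- normalizers[[f]]
      if (is.null(b) || !is.finite(b[1]) || !is.finite(b[2]) || b[1] >= b[2]) {
        stop("total_stress: invalid normalizer bounds for '", f, "'", call. = FALSE)
      }
      v <- (v - b[1]) / (b[2] - b[1])
    }
    v
  }, numeric(1))
  s <- sum(w * vals)
  min(max(s, 0), 1)
}

#' Z-shaped fuzzy membership function
#'
#' \deqn{zmf(s) = 1 \;(s \le a);\quad 1 - 2\big(\tfrac{s-a}{b-a}\big)^2
#'   \;(a \le s \le \tfrac{a+b}{2});\quad 2\big(\tfrac{s-b}{b-a}\big)^2
#'   \;(\tfrac{a+b}{2} \le s \le b);\quad 0 \;(s \ge b).}
#' Continuous and nonincreasing, mapping total stress to health quality in
#' [0, 1]; `zmf(a) = 1`, `zmf((a+b)/2) = 0.5`, `zmf(b) = 0`.
#'
#' @param s Total stress value(s).
#' @param a,b Adjustment coefficients with `a < b` (published fits: zone
#'   1-3 degrees C a = 0.019, zone 3-6 degrees C a = 0.0138, b = 1).
#' @return Membership value(s) in [0, 1].
#' @export
zmf <- function(s, a, b) {
  stopifnot(a < b)
  mid <- (a + b) / 2
  out <- numeric(length(s))
  lo <- s <= a
  up <- s >= b
  m1 <- !lo & s <= mid
  m2 <- !up & s > mid
  out[lo] <- 1
  out[m1] <- 1 - 2 * ((s[m1] - a) / (b - a))^2
  out[m2] <- 2 * ((s[m2] - b) / (b - a))^2
  out[up] <- 0
  out
}

#' Fit the ZMF adjustment coefficient by curve enclosure
#'
#' With `b` fixed, `zmf(s; a, b)` is nondecreasing in `a` for any fixed `s`,
#' so the tightest curve lying on or above all points (the smallest such
#' `a`) and the tightest curve lying on or below all points (the largest
#' such `a`) can each be found by monotone bisection; the fitted coefficient
#' is the mean of the two enclosing curves' parameters.  On points sampled
#' exactly from a ZMF the two envelopes coincide at the true `a`.
#'
#' @param total_stress Stress coordinates of the detection points, in [0, 1].
#' @param score Health scores of the points, in [0, 1].
#' @param b_fixed Fixed upper coefficient (default 1).
#' @param tol Bisection tolerance on `a` (default 1e-9).
#' @return A list with `a`, `b`, `a_upper`, `a_lower`.
#' @export
fit_zmf_envelope <- function(total_stress, score, b_fixed = 1, tol = 1e-9) {
  stopifnot(length(total_stress) == length(score))
  if (length(total_stress) < 1) stop("fit_zmf_envelope: no points", call. = FALSE)
  if (any(score < 0 | score > 1)) {
    stop("fit_zmf_envelope: scores must lie in [0, 1]", call. = FALSE)
  }
  a_min <- -b_fixed + 1e-12
  a_max <- b_fixed - 1e-12
  # scores saturated at the membership bounds are censored on the side they
  # saturate: a score of exactly 1 (0) carries no information about how far
  # above (below) the curve must pass
  up_pts <- score < 1
  lo_pts <- score > 0
  above <- function(a) {
    all(zmf(total_stress[up_pts], a, b_fixed) >= score[up_pts] - 1e-12)
  }
  below <- function(a) {
    all(zmf(total_stress[lo_pts], a, b_fixed) <= score[lo_pts] + 1e-12)
  }
  if (!above(a_max) || !below(a_min)) {
    stop("fit-failure: no enclosing ZMF pair exists within a in (-b, b)",
         call. = FALSE)
  }
  # smallest a whose curve lies above all points
  lo <- a_min; hi <- a_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (above(mid)) hi <- mid else lo <- mid
  }
  a_upper <- hi
  # largest a whose curve lies below all points
  lo <- a_min; hi <- a_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (below(mid)) lo <- mid else hi <- mid
  }
  a_lower <- lo
  degenerate <- a_upper <= a_min + 2 * tol && a_lower >= a_max - 2 * tol
  if (degenerate) {
    warning("fit_zmf_envelope: every curve encloses the points; returning ",
            "the search-interval midpoint")
  }
  list(a = (a_upper + a_lower) / 2, b = b_fixed,
       a_upper = a_upper, a_lower = a_lower)
}

#' Classify average total stress into a health level
#'
#' Levels follow the zone's stress intervals, left-closed and right-open:
#' e.g. for 1-3 degrees C, SLL on [0, 0.406), MLL on [0.406, 0.625), BLL on
#' [0.625, 0.783), WLL on [0.783, 0.792), DS on [0.792, 1].
#'
#' @param total_stress_avg Average total stress in [0, 1] (vectorised).
#' @param thresholds A [level_thresholds()] list (or a zone name).
#' @return Factor of levels (`SLL`, `MLL`, `BLL`, `WLL`, `DS`).
#' @export
classify_health <- function(total_stress_avg, thresholds = level_thresholds()) {
  if (is.character(thresholds)) thresholds <- level_thresholds(thresholds)
  stopifnot(all(total_stress_avg >= 0 & total_stress_avg <= 1))
  idx <- findInterval(total_stress_avg, thresholds$stress_breaks,
                      left.open = FALSE) + 1L
  factor(HEALTH_LEVELS[idx], levels = HEALTH_LEVELS)
}

#' Full health assessment of a total-stress trajectory
#'
#' For each time point, the running average of total stress since monitoring
#' start (the default averaging window) is mapped through the zone's ZMF to
#' a health-quality value and classified into a level.
#'
#' @param time_h Time points (hours).
#' @param total_stress_t Total stress values in [0, 1] at those times.
#' @param zone Temperature zone name.
#' @param cumulative_average Use the running mean since start for
#'   classification (default TRUE); otherwise the instantaneous value.
#' @return A data.frame `time_h`, `total_stress`, `avg_stress`, `hq`,
#'   `level`, `zone`.
#' @export
assess_health <- function(time_h, total_stress_t,
                          zone = c("ZONE_1_3", "ZONE_3_6"),
                          cumulative_average = TRUE) {
  zone <- match.arg(zone)
  th <- level_thresholds(zone)
  avg <- if (cumulative_average) {
    cumsum(total_stress_t) / seq_along(total_stress_t)
  } else total_stress_t
  avg <- pmin(pmax(avg, 0), 1)
  data.frame(time_h = time_h, total_stress = total_stress_t,
             avg_stress = avg, hq = zmf(avg, th$a, th$b),
             level = classify_health(avg, th), zone = zone)
}

#' Near-death time point from a cohort death schedule
#'
#' The first observation checkpoint at which the cohort survival rate drops
#' below the threshold (default 60%).
#'
#' @param schedule data.frame with `checkpoint_hour` and nondecreasing
#'   `cumulative_deaths` (e.g. from [death_schedule()]).
#' @param cohort Cohort size (>= deaths).
#' @param survival_threshold Stopping threshold on the survival fraction
#'   (default 0.60).
#' @return A list `(hour, survival_rate)`, or `NULL` if the threshold is
#'   never crossed.
#' @export
near_death_point <- function(schedule, cohort, survival_threshold = 0.60) {
  stopifnot(is.data.frame(schedule),
            all(c("checkpoint_hour", "cumulative_deaths") %in% names(schedule)))
  d <- schedule$cumulative_deaths
  if (any(diff(d) < 0) || any(d > cohort) || any(d < 0)) {
    stop("malformed schedule: deaths must be nondecreasing and <= cohort",
         call. = FALSE)
  }
  surv <- (cohort - d) / cohort
  hit <- which(surv < survival_threshold)
  if (!length(hit)) return(NULL)
  list(hour = schedule$checkpoint_hour[hit[1]], survival_rate = surv[hit[1]])
}
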
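# Seeded synthetic WBIA experiments with known ground truth.
#
# The generator emulates the waterless low-temperature monitoring design:
# fish are chilled into cold dormancy and held at 1-3 or 3-6 degrees C for
# ~84 h while a wearable sweeps 30-100 kHz every few minutes; serum/muscle
# biomarkers are assayed only at sparse checkpoint hours.

#' Simulation configuration for a synthetic WBIA experiment
#'
#' @param duration_hours Run length in hours (default 84, the near-death
#'   horizon of the monitoring design).
#' @param sample_interval_minutes WBIA sampling interval (default 5).
#' @param frequencies_khz Ordered sweep frequencies (default 30-100 kHz in
#'   10 kHz steps).
#' @param coupled_frequencies_khz Subset of `frequencies_khz` whose impedance
#'   and phase are driven by total stress (default 70, 80, 90, 100).
#' @param temp_zone `"ZONE_1_3"` (1-3 degrees C) or `"ZONE_3_6"` (3-6
#'   degrees C); the warmer zone has a strictly faster mean stress rise.
#' @param noise_sd Gaussian sensor noise SD on the raw real/imaginary
#'   channels, in ohm (default 2).
#' @param gross_error_rate Per-sample, per-channel probability of an injected
#'   gross error (default 0.01).
#' @param gross_error_magnitude_sd Spike magnitude in multiples of
#'   `noise_sd` (default 10).
#' @param checkpoint_hours Biomarker assay hours (default the monitoring
#'   scheme 0, 12, 18, 24, 48, 60, 72, 84, truncated to the duration).
#' @param seed Integer seed; identical config + seed reproduces the
#'   experiment byte-identically.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_hours = 84,
                              sample_interval_minutes = 5,
                              frequencies_khz = seq(30, 100, by = 10),
                              coupled_frequencies_khz = c(70, 80, 90, 100),
                              temp_zone = c("ZONE_1_3", "ZONE_3_6"),
                              noise_sd = 2,
                              gross_error_rate = 0.01,
                              gross_error_magnitude_sd = 10,
                              checkpoint_hours = c(0, 12, 18, 24, 48, 60, 72, 84),
                              seed = 1L) {
  temp_zone <- match.arg(temp_zone)
  if (!is.numeric(duration_hours) || duration_hours <= 0) {
    stop("configuration error: duration_hours must be positive", call. = FALSE)
  }
  if (!is.numeric(sample_interval_minutes) || sample_interval_minutes <= 0) {
    stop("configuration error: sample_interval_minutes must be positive", call. = FALSE)
  }
  if (duration_hours * 60 / sample_interval_minutes < 1) {
    stop("configuration error: duration/interval must yield at least 2 samples",
         call. = FALSE)
  }
  if (is.unsorted(frequencies_khz, strictly = TRUE)) {
    stop("configuration error: frequencies_khz must be strictly increasing",
         call. = FALSE)
  }
  if (!all(coupled_frequencies_khz %in% frequencies_khz)) {
    stop("configuration error: coupled_frequencies_khz must be a subset of frequencies_khz",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("configuration error: noise_sd must be nonnegative", call. = FALSE)
  }
  if (gross_error_rate < 0 || gross_error_rate > 1) {
    stop("configuration error: gross_error_rate must be in [0, 1]", call. = FALSE)
  }
  if (gross_error_magnitude_sd <= 0) {
    stop("configuration error: gross_error_magnitude_sd must be positive", call. = FALSE)
  }
  checkpoint_hours <- checkpoint_hours[checkpoint_hours <= duration_hours]
  structure(
    list(duration_hours = duration_hours,
         sample_interval_minutes = sample_interval_minutes,
         frequencies_khz = frequencies_khz,
         coupled_frequencies_khz = coupled_frequencies_khz,
         temp_zone = temp_zone,
         noise_sd = noise_sd,
         gross_error_rate = gross_error_rate,
         gross_error_magnitude_sd = gross_error_magnitude_sd,
         checkpoint_hours = checkpoint_hours,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Logistic saturating-growth curves for the three stress factors.  Baselines
# and plateaus are typical assay scales for cold-stressed flatfish: glucose
# 3 -> 9 mmol/L serum, lactate 2 -> 12 mmol/kg muscle, cortisol
# 20 -> 180 ng/mL serum.  The warmer zone rises faster and earlier.
stress_curve_params <- function(temp_zone) {
  speed <- if (temp_zone == "ZONE_3_6") 1.6 else 1.0
  t_mid <- if (temp_zone == "ZONE_3_6") 34 else 42
  list(
    glucose  = list(s0 = 3,  s_max = 9,   k = 0.075 * speed, t_mid = t_mid),
    lactate  = list(s0 = 2,  s_max = 12,  k = 0.090 * speed, t_mid = t_mid - 4),
    cortisol = list(s0 = 20, s_max = 180, k = 0.080 * speed, t_mid = t_mid + 2)
  )
}

logistic_curve <- function(t, p) {
  p$s0 + (p$s_max - p$s0) / (1 + exp(-p$k * (t - p$t_mid)))
}

# Exponential decay toward a floor for the declining muscle nutrients.
nutrient_curve_params <- function(temp_zone) {
  speed <- if (temp_zone == "ZONE_3_6") 1.4 else 1.0
  list(
    glycogen      = list(init = 8.0,  floor = 1.5,  rate = 0.030 * speed),
    fat           = list(init = 52,   floor = 38,   rate = 0.018 * speed),
    crude_protein = list(init = 185,  floor = 160,  rate = 0.012 * speed),
    atp_compounds = list(init = 5.2,  floor = 1.2,  rate = 0.028 * speed),
    ph            = list(init = 7.25, floor = 6.35, rate = 0.022 * speed)
  )
}

decay_curve <- function(t, p) p$floor + (p$init - p$floor) * exp(-p$rate * t)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a complete synthetic WBIA experiment
#'
#' Generates (i) noiseless logistic stress trajectories with zone-dependent
#' rates and exponentially declining muscle nutrients; (ii) multifrequency
#' sweep frames in which the impedance magnitude and phase at each coupled
#' frequency are affine functions of normalized total stress plus Gaussian
#' sensor noise, while uncoupled frequencies fluctuate around constants;
#' (iii) isolated gross-error spikes of \eqn{\pm} `gross_error_magnitude_sd`
#' \eqn{\times} `noise_sd` at the configured rate, with every injected
#' position recorded; and (iv) sparse noisy biomarker/nutrient checkpoints.
#'
#' The direction of the stress-impedance coupling (impedance rises with
#' stress, as progressive dehydration raises tissue impedance) is a simulator
#' convention, not a biological claim.
#'
#' @param config A [simulation_config()].
#' @return A list of class `wbia_simulation` with elements `sweeps`
#'   (a [sweep_frames()] table), `stress` (checkpoint [stress_series()]),
#'   `nutrients` (checkpoint [nutrient_panel()]), and `ground_truth` (list
#'   with the dense noiseless `stress` series, dense noiseless `nutrients`,
#'   normalized `total_stress01`, `outlier_positions` data.frame
#'   (`time_index`, `frequency_khz`, `channel`), `coupling_coefficients`,
#'   and the sampling grid `time_h`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    time_h <- seq(0, config$duration_hours,
                  by = config$sample_interval_minutes / 60)
    n_t <- length(time_h)
    freqs <- config$frequencies_khz
    n_f <- length(freqs)

    sp <- stress_curve_params(config$temp_zone)
    stress_true <- lapply(sp, function(p) logistic_curve(time_h, p))
    stress01 <- vapply(names(sp), function(f) {
      p <- sp[[f]]
      (stress_true[[f]] - p$s0) / (p$s_max - p$s0)
    }, numeric(n_t))
    total01 <- rowMeans(stress01)

    np <- nutrient_curve_params(config$temp_zone)
    nutrients_true <- lapply(np, function(p) decay_curve(time_h, p))
    nutrients_true$muscle_lactate <- stress_true$lactate

    # Channel baselines: impedance ~ 450 + f ohm, phase ~ -0.35 + 0.001 f rad.
    z0 <- 450 + freqs
    th0 <- -0.35 + 0.001 * freqs
    coupled <- freqs %in% config$coupled_frequencies_khz
    cz <- ifelse(coupled, 0.30, 0)     # relative impedance rise at full stress
    cth <- ifelse(coupled, -0.12, 0)   # phase shift (rad) at full stress

    base_temp <- if (config$temp_zone == "ZONE_3_6") 4.5 else 2.0
    temperature <- base_temp + 0.3 * sin(2 * pi * time_h / 24) +
      rnorm(n_t, sd = 0.05)

    z_clean <- outer(total01, cz * z0) + rep(z0, each = n_t)       # n_t x n_f
    th_clean <- outer(total01, cth) + rep(th0, each = n_t)
    r_clean <- z_clean * cos(th_clean)
    i_clean <- z_clean * sin(th_clean)

    r_obs <- r_clean + rnorm(n_t * n_f, sd = config$noise_sd)
    i_obs <- i_clean + rnorm(n_t * n_f, sd = config$noise_sd)

    # Gross errors replace the Gaussian noise at the hit sample with an exact
    # +-(magnitude * noise_sd) spike, so every recorded outlier deviates from
    # the noiseless value by exactly that amount.
    outliers <- data.frame(time_index = integer(), frequency_khz = numeric(),
                           channel = character())
    if (config$gross_error_rate > 0 && config$noise_sd > 0) {
      spike <- config$gross_error_magnitude_sd * config$noise_sd
      for (channel in c("r", "i")) {
        hit <- which(runif(n_t * n_f) < config$gross_error_rate)
        if (length(hit)) {
          signs <- sample(c(-1, 1), length(hit), replace = TRUE)
          idx_t <- ((hit - 1) %% n_t) + 1
          idx_f <- ((hit - 1) %/% n_t) + 1
          if (channel == "r") r_obs[hit] <- r_clean[hit] + signs * spike
          else                i_obs[hit] <- i_clean[hit] + signs * spike
          outliers <- rbind(outliers, data.frame(
            time_index = idx_t, frequency_khz = freqs[idx_f], channel = channel))
        }
      }
    }

    t0 <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")
    timestamps <- t0 + time_h * 3600
    frames <- sweep_frames(
      timestamp = rep(timestamps, times = n_f),
      frequency_khz = rep(freqs, each = n_t),
      r_ohm = as.vector(r_obs),
      i_ohm = as.vector(i_obs),
      temperature_c = rep(temperature, times = n_f)
    )

    # Sparse noisy biomarker checkpoints (assay CV ~ 2% of dynamic range).
    cp <- config$checkpoint_hours
    cp_idx <- vapply(cp, function(h) which.min(abs(time_h - h)), 1L)
    obs_stress <- lapply(names(sp), function(f) {
      p <- sp[[f]]
      stress_true[[f]][cp_idx] + rnorm(length(cp), sd = 0.02 * (p$s_max - p$s0))
    })
    names(obs_stress) <- names(sp)
    obs_nutrients <- lapply(names(nutrients_true), function(nm) {
      v <- nutrients_true[[nm]][cp_idx]
      v + rnorm(length(cp), sd = 0.02 * abs(diff(range(nutrients_true[[nm]]))))
    })
    names(obs_nutrients) <- names(nutrients_true)

    structure(list(
      sweeps = frames,
      stress = stress_series(cp, obs_stress$glucose, obs_stress$lactate,
                             obs_stress$cortisol),
      nutrients = nutrient_panel(cp, obs_nutrients),
      ground_truth = list(
        time_h = time_h,
        stress = stress_series(time_h, stress_true$glucose,
                               stress_true$lactate, stress_true$cortisol),
        nutrients = nutrient_panel(time_h, nutrients_true),
        total_stress01 = total01,
        outlier_positions = outliers,
        coupling_coefficients = setNames(cz, freqs)
      ),
      config = config
    ), class = "wbia_simulation")
  })
}

#' Cohort death schedule over observation checkpoints
#'
#' In fixture mode (`hazard_per_hour = NULL`) the printed observation
#' schedule of the monitoring study is returned: out of a cohort observed at
#' 60, 72, 78 and 84 h, 2, 3, 3 and 3 further fish are found dead at the
#' successive checkpoints (capped at `cohort_size`).  In random mode, deaths
#' per interval are binomial among survivors with the given constant hazard,
#' deterministic under the config seed.
#'
#' @param config A [simulation_config()] (supplies the seed).
#' @param cohort_size Number of fish observed (>= 1).
#' @param checkpoint_hours Observation checkpoints (default 60, 72, 78, 84).
#' @param hazard_per_hour `NULL` for fixture mode, or a nonnegative constant
#'   per-hour death hazard.
#' @return A data.frame with columns `checkpoint_hour` and
#'   `cumulative_deaths` (nondecreasing, bounded by `cohort_size`).
#' @export
death_schedule <- function(config, cohort_size,
                           checkpoint_hours = c(60, 72, 78, 84),
                           hazard_per_hour = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(cohort_size) || cohort_size < 1) {
    stop("cohort_size must be a positive integer", call. = FALSE)
  }
  if (is.null(hazard_per_hour)) {
    new_deaths <- c(2, 3, 3, 3)[seq_along(checkpoint_hours)]
    new_deaths[is.na(new_deaths)] <- 0
    cum <- pmin(cumsum(new_deaths), cohort_size)
  } else {
    stopifnot(hazard_per_hour >= 0)
    cum <- with_seed(config$seed, {
      alive <- cohort_size
      dt <- diff(c(0, checkpoint_hours))
      out <- numeric(length(checkpoint_hours))
      dead <- 0
      for (j in seq_along(checkpoint_hours)) {
        p <- 1 - exp(-hazard_per_hour * dt[j])
        d <- rbinom(1, alive, p)
        dead <- dead + d
        alive <- alive - d
        out[j] <- dead
      }
      out
    })
  }
  data.frame(checkpoint_hour = checkpoint_hours, cumulative_deaths = cum)
}

#' Write a simulated experiment to disk
#'
#' Emits the sweep CSV, biomarker and nutrient checkpoint CSVs, the dense
#' ground-truth CSV pair, and a JSON manifest echoing the configuration and
#' seed.
#'
#' @param sim A `wbia_simulation` from [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "wbia_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sweeps(sim$sweeps, file.path(dir, "sweeps.csv"))
  write_checkpoints(sim$stress, file.path(dir, "stress_checkpoints.csv"))
  write_checkpoints(sim$nutrients, file.path(dir, "nutrient_checkpoints.csv"))
  write_checkpoints(sim$ground_truth$stress, file.path(dir, "truth_stress.csv"))
  write_checkpoints(sim$ground_truth$nutrients, file.path(dir, "truth_nutrients.csv"))
  write.csv(sim$ground_truth$outlier_positions,
            file.path(dir, "truth_outliers.csv"), row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(list(seed = cfg$seed, config = cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
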
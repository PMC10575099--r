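#' Impedance magnitude and phase from a raw sweep reading
#'
#' A WBIA sweep returns, at each frequency, the real part \eqn{R} and
#' imaginary part \eqn{I} of the complex reading.  Magnitude is
#' \eqn{M = \sqrt{R^2 + I^2}} and phase is the principal value
#' \eqn{\theta = \arctan(I/R)}.  Quadrant information is deliberately not
#' recovered: the device convention reports phase in \eqn{(-\pi/2, \pi/2]},
#' with \eqn{\theta = \pm\pi/2} when \eqn{R = 0} by the sign of \eqn{I}.
#'
#' @param r_ohm Real part of the reading (vectorised).
#' @param i_ohm Imaginary part of the reading (vectorised).
#' @return A list with numeric vectors `magnitude` and `phase_rad`.
#' @examples
#' magnitude_phase(3, 4)   # 3-4-5 triangle: magnitude 5, phase atan(4/3)
#' @export
magnitude_phase <- function(r_ohm, i_ohm) {
  stopifnot(is.numeric(r_ohm), is.numeric(i_ohm), length(r_ohm) == length(i_ohm))
  if (any(r_ohm == 0 & i_ohm == 0)) {
    stop("degenerate sweep reading: r_ohm and i_ohm are both zero", call. = FALSE)
  }
  magnitude <- sqrt(r_ohm^2 + i_ohm^2)
  phase <- ifelse(r_ohm == 0, sign(i_ohm) * pi / 2, atan(i_ohm / r_ohm))
  list(magnitude = magnitude, phase_rad = phase)
}

#' Gain-factor calibration against a known reference resistor
#'
#' The per-frequency gain factor \eqn{K} is obtained from the measured
#' magnitude of a known resistor so that \eqn{Z = 1/(M K)} returns the
#' reference resistance when \eqn{M} equals the reference magnitude:
#' \eqn{K = 1/(M_{ref} \cdot Z_{ref})}.
#'
#' @param reference_magnitude Measured magnitude on the reference resistor (> 0).
#' @param reference_ohm Known resistance in ohm (> 0), e.g. 1000 for a 1 kOhm
#'   reference.
#' @return An object of class `calibration_factor` with fields `gain_k` and
#'   `reference_ohm`.
#' @seealso [apply_calibration()]
#' @export
calibrate <- function(reference_magnitude, reference_ohm) {
  if (!is.numeric(reference_magnitude) || any(reference_magnitude <= 0)) {
    stop("calibration error: reference_magnitude must be positive", call. = FALSE)
  }
  if (!is.numeric(reference_ohm) || any(reference_ohm <= 0)) {
    stop("calibration error: reference_ohm must be positive", call. = FALSE)
  }
  structure(
    list(gain_k = 1 / (reference_magnitude * reference_ohm),
         reference_ohm = reference_ohm),
    class = "calibration_factor"
  )
}

#' Apply a gain factor to measured magnitudes
#'
#' @param magnitude Measured magnitudes (> 0).
#' @param cal A `calibration_factor` from [calibrate()].
#' @return Calibrated impedance in ohm, `1 / (magnitude * gain_k)`.
#' @export
apply_calibration <- function(magnitude, cal) {
  stopifnot(inherits(cal, "calibration_factor"))
  if (any(magnitude <= 0)) stop("calibration error: magnitude must be positive", call. = FALSE)
  1 / (magnitude * cal$gain_k)
}

#' Construct a sweep-frame table
#'
#' A sweep-frame table holds one row per (timestamp, frequency) with the raw
#' real/imaginary readings, the fish-surface temperature and the derived
#' magnitude and phase.  Timestamps are POSIXct UTC; frequencies are kHz.
#'
#' @param timestamp POSIXct vector (recycled against frequencies as needed).
#' @param frequency_khz Numeric frequencies in kHz.
#' @param r_ohm,i_ohm Raw sweep readings.
#' @param temperature_c Temperature in degrees Celsius.
#' @return A `data.frame` of class `sweep_frames`, ordered by timestamp then
#'   frequency, with derived `magnitude` and `phase_rad` columns.
#' @export
sweep_frames <- function(timestamp, frequency_khz, r_ohm, i_ohm, temperature_c) {
  df <- data.frame(timestamp = timestamp, frequency_khz = frequency_khz,
                   r_ohm = r_ohm, i_ohm = i_ohm, temperature_c = temperature_c)
  df <- df[order(df$timestamp, df$frequency_khz), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3"), df$frequency_khz)
  if (anyDuplicated(key)) {
    stop("format error: duplicate (timestamp, frequency) row at input line ",
         which(duplicated(key))[1], call. = FALSE)
  }
  mp <- magnitude_phase(df$r_ohm, df$i_ohm)
  df$magnitude <- mp$magnitude
  df$phase_rad <- mp$phase_rad
  class(df) <- c("sweep_frames", "data.frame")
  df
}

#' Write sweep frames to CSV
#'
#' Columns: `timestamp_iso, frequency_khz, r_ohm, i_ohm, temperature_c`.
#'
#' @param frames A `sweep_frames` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(frames, path) {
  stopifnot(inherits(frames, "sweep_frames"))
  out <- data.frame(
    timestamp_iso = format(frames$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    frequency_khz = frames$frequency_khz,
    r_ohm = frames$r_ohm,
    i_ohm = frames$i_ohm,
    temperature_c = frames$temperature_c
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Read a delimited file accepting comma or tab; returns a data.frame.
read_delim_auto <- function(path, required) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("format error in '", path, "': missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read sweep frames from CSV
#'
#' Accepts comma- or tab-delimited files with columns
#' `timestamp_iso, frequency_khz, r_ohm, i_ohm, temperature_c`.  Duplicate
#' (timestamp, frequency) rows and non-monotone timestamps are rejected with
#' the offending line number (header is line 1).
#'
#' @param path CSV path.
#' @return A `sweep_frames` table.
#' @export
read_sweeps <- function(path) {
  df <- read_delim_auto(path, c("timestamp_iso", "frequency_khz", "r_ohm",
                                "i_ohm", "temperature_c"))
  if (nrow(df) == 0L) {
    return(sweep_frames(as.POSIXct(character(), tz = "UTC"), numeric(),
                        numeric(), numeric(), numeric()))
  }
  ts <- as.POSIXct(df$timestamp_iso, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("format error in '", path, "': unparseable timestamp at line ",
         bad[1] + 1L, call. = FALSE)
  }
  key <- paste(df$timestamp_iso, df$frequency_khz)
  if (anyDuplicated(key)) {
    stop("format error in '", path, "': duplicate (timestamp, frequency) at line ",
         which(duplicated(key))[1] + 1L, call. = FALSE)
  }
  if (is.unsorted(ts)) {
    stop("format error in '", path, "': non-monotone timestamps at line ",
         which(diff(as.numeric(ts)) < 0)[1] + 2L, call. = FALSE)
  }
  sweep_frames(ts, df$frequency_khz, df$r_ohm, df$i_ohm, df$temperature_c)
}

STRESS_FACTORS <- c("glucose", "lactate", "cortisol")
NUTRIENTS <- c("glycogen", "fat", "crude_protein", "atp_compounds", "ph",
               "muscle_lactate")

#' Construct a stress series
#'
#' Time-indexed serum glucose, muscle lactate and serum cortisol values.
#'
#' @param time_h Ordered time points in hours.
#' @param glucose,lactate,cortisol Numeric vectors, one value per time point.
#' @param normalized Logical; `TRUE` once values are min-max scaled to [0, 1].
#' @param units Named character vector of units per factor.
#' @return A `data.frame` of class `stress_series`.
#' @export
stress_series <- function(time_h, glucose, lactate, cortisol,
                          normalized = FALSE,
                          units = c(glucose = "mmol/L", lactate = "mmol/kg",
                                    cortisol = "ng/mL")) {
  stopifnot(!is.unsorted(time_h),
            length(glucose) == length(time_h),
            length(lactate) == length(time_h),
            length(cortisol) == length(time_h))
  df <- data.frame(time_h = time_h, glucose = glucose, lactate = lactate,
                   cortisol = cortisol)
  if (normalized) {
    vals <- unlist(df[STRESS_FACTORS])
    stopifnot(all(vals >= -1e-9 & vals <= 1 + 1e-9))
  }
  attr(df, "normalized") <- normalized
  attr(df, "units") <- units
  class(df) <- c("stress_series", "data.frame")
  df
}

#' Construct a nutrient panel
#'
#' Time-indexed muscle nutrient values used for health scoring and GRA
#' weighting: glycogen, fat, crude protein, ATP-related compounds, pH and
#' muscle lactate.
#'
#' @param time_h Ordered time points in hours.
#' @param values A data.frame or named list with one numeric vector per
#'   nutrient in [NUTRIENTS].
#' @param units Named character vector of units per nutrient.
#' @return A `data.frame` of class `nutrient_panel`.
#' @export
nutrient_panel <- function(time_h, values,
                           units = c(glycogen = "mg/g", fat = "mg/g",
                                     crude_protein = "mg/g",
                                     atp_compounds = "umol/g", ph = "pH",
                                     muscle_lactate = "mmol/kg")) {
  values <- as.data.frame(values)
  stopifnot(!is.unsorted(time_h), all(NUTRIENTS %in% names(values)),
            all(vapply(values, length, 1L) == length(time_h)))
  df <- cbind(data.frame(time_h = time_h), values[NUTRIENTS])
  attr(df, "units") <- units
  class(df) <- c("nutrient_panel", "data.frame")
  df
}

#' Write a checkpoint table (stress series or nutrient panel) to CSV
#'
#' Long format with columns `time_h, analyte, value, units`.
#'
#' @param x A `stress_series` or `nutrient_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_checkpoints <- function(x, path) {
  stopifnot(inherits(x, "stress_series") || inherits(x, "nutrient_panel"))
  analytes <- setdiff(names(x), "time_h")
  units <- attr(x, "units")
  long <- do.call(rbind, lapply(analytes, function(a) {
    data.frame(time_h = x$time_h, analyte = a, value = x[[a]],
               units = unname(units[a]))
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a checkpoint CSV as a stress series or nutrient panel
#'
#' The analyte set determines the return type: the three stress factors give
#' a `stress_series`, the nutrient set gives a `nutrient_panel`.
#'
#' @param path CSV path with columns `time_h, analyte, value, units`.
#' @return A `stress_series` or `nutrient_panel`.
#' @export
read_checkpoints <- function(path) {
  df <- read_delim_auto(path, c("time_h", "analyte", "value"))
  analytes <- sort(unique(df$analyte))
  wide <- lapply(analytes, function(a) {
    sub <- df[df$analyte == a, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    sub
  })
  names(wide) <- analytes
  times <- wide[[1]]$time_h
  for (w in wide) {
    if (!identical(w$time_h, times)) {
      stop("format error in '", path, "': analytes have unequal time grids",
           call. = FALSE)
    }
  }
  units <- vapply(wide, function(w) {
    if ("units" %in% names(w)) as.character(w$units[1]) else NA_character_
  }, character(1))
  vals <- lapply(wide, function(w) w$value)
  if (setequal(analytes, STRESS_FACTORS)) {
    stress_series(times, vals$glucose, vals$lactate, vals$cortisol,
                  units = units[STRESS_FACTORS])
  } else if (all(NUTRIENTS %in% analytes)) {
    nutrient_panel(times, vals[NUTRIENTS], units = units[NUTRIENTS])
  } else {
    stop("format error in '", path, "': analyte set matches neither the ",
         "stress factors nor the nutrient panel", call. = FALSE)
  }
}
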
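#' Published MIC reference tables from the turbot monitoring study
#'
#' The printed MIC values between each WBIA feature (impedance and phase at
#' 30-100 kHz) and the three stress factors, shipped as plain-text CSVs.
#' Applying [screen_features()] at threshold 0.9 to these matrices selects
#' impedance at 80, 90 and 100 kHz and phase at 70, 80 and 90 kHz.
#'
#' @return A list with two matrices, `impedance` and `phase`, rows labelled
#'   `impedance_<f>` / `phase_<f>`, columns the stress factors.
#' @export
mic_reference_tables <- function() {
  load_one <- function(file, prefix) {
    path <- system.file("extdata", file, package = "aquavital", mustWork = TRUE)
    df <- read.csv(path)
    m <- as.matrix(df[STRESS_FACTORS])
    rownames(m) <- paste0(prefix, "_", df$frequency_khz)
    m
  }
  list(impedance = load_one("mic_reference_impedance.csv", "impedance"),
       phase = load_one("mic_reference_phase.csv", "phase"))
}
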
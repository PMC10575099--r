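test_that("magnitude and phase follow the sweep conversion identities", {
  mp <- magnitude_phase(3, 4)
  expect_equal(mp$magnitude, 5)
  expect_equal(mp$phase_rad, atan(4 / 3))

  expect_equal(magnitude_phase(1, 0), list(magnitude = 1, phase_rad = 0))

  mp <- magnitude_phase(-1, 1)
  expect_equal(mp$magnitude, sqrt(2))
  expect_equal(mp$phase_rad, -pi / 4)  # principal value: quadrant is lost

  # r = 0 convention: +- pi/2 by the sign of the imaginary part
  expect_equal(magnitude_phase(0, 2)$phase_rad, pi / 2)
  expect_equal(magnitude_phase(0, -2)$phase_rad, -pi / 2)
  expect_error(magnitude_phase(0, 0), "degenerate")
})

test_that("calibration inverts the gain relation Z = 1/(M K)", {
  cal <- calibrate(0.001, 1000)
  expect_equal(cal$gain_k, 1.0)
  expect_equal(apply_calibration(0.0005, cal), 2000)

  cal1 <- calibrate(1, 1)
  expect_equal(cal1$gain_k, 1)
  expect_equal(apply_calibration(4, cal1), 0.25)

  # round trip at arbitrary reference values, exact to float precision
  for (m_ref in c(1e-4, 0.02, 3)) {
    cal <- calibrate(m_ref, 1500)
    expect_equal(apply_calibration(m_ref, cal), 1500)
  }
  expect_error(calibrate(-1, 10), "calibration error")
  expect_error(calibrate(1, 0), "calibration error")
})

test_that("parsed frames satisfy the magnitude/phase invariants", {
  sim <- simulate_experiment(small_sim_config(seed = 4))
  fr <- sim$sweeps
  expect_true(all(abs(fr$magnitude^2 - (fr$r_ohm^2 + fr$i_ohm^2)) <=
                    1e-9 * fr$magnitude^2))
  expect_true(all(fr$phase_rad > -pi / 2 & fr$phase_rad < pi / 2))
})

test_that("sweep CSV write/read round-trips a simulated run", {
  sim <- simulate_experiment(small_sim_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(sim$sweeps, path)
  back <- read_sweeps(path)
  expect_equal(back$frequency_khz, sim$sweeps$frequency_khz)
  expect_equal(back$r_ohm, sim$sweeps$r_ohm, tolerance = 1e-6)
  expect_equal(back$i_ohm, sim$sweeps$i_ohm, tolerance = 1e-6)
  expect_equal(as.numeric(back$timestamp), as.numeric(sim$sweeps$timestamp))
})

test_that("malformed sweep CSVs are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_iso,frequency_khz,r_ohm,i_ohm,temperature_c",
               "2026-01-05T00:00:00Z,30,450,-150,2.0",
               "2026-01-05T00:00:00Z,30,451,-151,2.0"), path)
  expect_error(read_sweeps(path), "duplicate.*line 3")

  writeLines(c("timestamp_iso,frequency_khz,r_ohm,i_ohm,temperature_c",
               "2026-01-05T01:00:00Z,30,450,-150,2.0",
               "2026-01-05T00:00:00Z,30,451,-151,2.0"), path)
  expect_error(read_sweeps(path), "non-monotone")

  writeLines(c("timestamp_iso,frequency_khz,r_ohm,i_ohm", "x,30,1,1"), path)
  expect_error(read_sweeps(path), "missing required column")

  # header-only file: empty frame, no error
  writeLines("timestamp_iso,frequency_khz,r_ohm,i_ohm,temperature_c", path)
  expect_equal(nrow(read_sweeps(path)), 0)
})

test_that("checkpoint CSVs round-trip stress series and nutrient panels", {
  sim <- simulate_experiment(small_sim_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")

  write_checkpoints(sim$stress, path)
  s2 <- read_checkpoints(path)
  expect_s3_class(s2, "stress_series")
  expect_equal(s2$lactate, sim$stress$lactate, tolerance = 1e-9)

  write_checkpoints(sim$nutrients, path)
  n2 <- read_checkpoints(path)
  expect_s3_class(n2, "nutrient_panel")
  expect_equal(n2$glycogen, sim$nutrients$glycogen, tolerance = 1e-9)

  # tab-delimited input is accepted
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- utils::read.csv(path)
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_checkpoints(tsv)$ph, n2$ph)
})
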
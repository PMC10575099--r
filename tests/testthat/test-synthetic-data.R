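test_that("identical config and seed reproduce the experiment exactly", {
  cfg <- small_sim_config(seed = 11)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$sweeps$r_ohm,
    simulate_experiment(small_sim_config(seed = 12))$sweeps$r_ohm))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simulation_config(duration_hours = -1), "duration_hours")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(gross_error_rate = 1.5), "gross_error_rate")
  expect_error(simulation_config(coupled_frequencies_khz = c(70, 110)),
               "coupled_frequencies_khz")
})

test_that("noiseless coupling makes impedance a monotone function of stress", {
  cfg <- small_sim_config(seed = 5, noise_sd = 0, gross_error_rate = 0)
  sim <- simulate_experiment(cfg)
  fm <- wbia_feature_matrix(sim$sweeps)
  stress <- sim$ground_truth$total_stress01
  for (f in cfg$coupled_frequencies_khz) {
    rho <- cor(fm[, paste0("impedance_", f)], stress, method = "spearman")
    expect_equal(rho, 1)
  }
  # uncoupled channels are exactly constant without noise
  expect_equal(sd(fm[, "impedance_30"]), 0)
})

test_that("stress rises, declining nutrients fall, and zones are ordered", {
  for (zone in c("ZONE_1_3", "ZONE_3_6")) {
    sim <- simulate_experiment(small_sim_config(seed = 8, temp_zone = zone))
    gt <- sim$ground_truth
    for (f in c("glucose", "lactate", "cortisol")) {
      expect_true(all(diff(gt$stress[[f]]) > 0))
    }
    for (nm in c("glycogen", "fat", "crude_protein", "atp_compounds", "ph")) {
      expect_true(all(diff(gt$nutrients[[nm]]) < 0))
    }
  }
  # warmer zone reaches strictly higher final mean stress across 20 seeds
  finals <- sapply(1:20, function(s) {
    c(cold = tail(simulate_experiment(
        simulation_config(seed = s, temp_zone = "ZONE_1_3")
      )$ground_truth$total_stress01, 1),
      warm = tail(simulate_experiment(
        simulation_config(seed = s, temp_zone = "ZONE_3_6")
      )$ground_truth$total_stress01, 1))
  })
  expect_gt(mean(finals["warm", ]), mean(finals["cold", ]))
})

test_that("injected gross errors are bookkept and exceed 5 noise SDs", {
  cfg <- small_sim_config(seed = 21, gross_error_rate = 0.02)
  sim <- simulate_experiment(cfg)
  clean <- simulate_experiment(
    small_sim_config(seed = 21, gross_error_rate = 0, noise_sd = 0))
  out <- sim$ground_truth$outlier_positions
  expect_gt(nrow(out), 0)
  times <- sort(unique(sim$sweeps$timestamp))
  devs <- vapply(seq_len(nrow(out)), function(k) {
    col <- if (out$channel[k] == "r") "r_ohm" else "i_ohm"
    row <- which(sim$sweeps$timestamp == times[out$time_index[k]] &
                   sim$sweeps$frequency_khz == out$frequency_khz[k])
    abs(sim$sweeps[[col]][row] - clean$sweeps[[col]][row])
  }, numeric(1))
  # every recorded spike deviates from the noiseless value by >= 5 noise SDs
  expect_true(all(devs >= 5 * cfg$noise_sd))
  # and non-outlier samples stay within 4 noise SDs almost surely
  key_out <- paste(out$time_index, out$frequency_khz, out$channel)
  row_key <- paste(match(sim$sweeps$timestamp, times),
                   sim$sweeps$frequency_khz, "r")
  dev_all <- abs(sim$sweeps$r_ohm - clean$sweeps$r_ohm)
  expect_gte(mean(dev_all[!(row_key %in% key_out)] < 4 * cfg$noise_sd), 0.999)
})

test_that("the death schedule reproduces the observation fixture and is seeded", {
  cfg <- small_sim_config(seed = 1)
  sched <- death_schedule(cfg, 25)
  expect_equal(sched$checkpoint_hour, c(60, 72, 78, 84))
  expect_equal(sched$cumulative_deaths, c(2, 5, 8, 11))

  # zero hazard: nobody dies
  zero <- death_schedule(cfg, 1, hazard_per_hour = 0)
  expect_equal(zero$cumulative_deaths, rep(0, 4))

  # random mode is reproducible and monotone, bounded by the cohort
  r1 <- death_schedule(cfg, 40, hazard_per_hour = 0.01)
  r2 <- death_schedule(cfg, 40, hazard_per_hour = 0.01)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$cumulative_deaths) >= 0))
  expect_true(all(r1$cumulative_deaths <= 40))
  expect_error(death_schedule(cfg, 0), "positive")
})

test_that("a written experiment directory contains the declared artifacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(small_sim_config(seed = 2))
  write_experiment(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "sweeps.csv", "stress_checkpoints.csv", "nutrient_checkpoints.csv",
    "truth_stress.csv", "truth_nutrients.csv", "truth_outliers.csv",
    "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2)
})
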
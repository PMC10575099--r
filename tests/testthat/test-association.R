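test_that("grey relational coefficients follow the resolution formula", {
  # identical series: zero deviation everywhere -> all coefficients 1
  x <- c(0.2, 0.5, 0.9)
  expect_equal(gra_coefficients(x, x), rep(1, 3))

  # single comparison with constant deviation: delta == delta_max everywhere
  expect_equal(gra_coefficients(c(0, 1), c(1, 0), rho = 0.5), c(1, 1))

  # nonincreasing in the deviation, holding the extrema fixed
  ref <- rep(0, 5)
  cmp <- c(0, 0.2, 0.5, 0.8, 1)
  z <- gra_coefficients(ref, cmp, rho = 0.5)
  expect_true(all(diff(z) <= 0))
  expect_true(all(z > 0 & z <= 1))

  expect_error(gra_coefficients(1:3, 1:4), "lengths differ")
})

test_that("stress weights normalize to 1 and respect symmetry", {
  sim <- simulate_experiment(small_sim_config(seed = 6))
  wv <- allocate_stress_weights(sim$stress, sim$nutrients)
  expect_s3_class(wv, "weight_vector")
  expect_equal(sum(wv$weights), 1, tolerance = 1e-9)
  expect_true(all(wv$relational_grades > 0 & wv$relational_grades <= 1))

  # two identical stress factors get identical weights
  s2 <- stress_series(sim$stress$time_h, sim$stress$lactate,
                      sim$stress$lactate, sim$stress$cortisol)
  wv2 <- allocate_stress_weights(s2, sim$nutrients)
  expect_equal(unname(wv2$weights["glucose"]), unname(wv2$weights["lactate"]),
               tolerance = 1e-12)

  # published fallback weights are a valid weight vector summing to 1
  dw <- default_stress_weights()
  expect_equal(unname(dw$weights), c(0.290, 0.396, 0.314))
  expect_equal(sum(dw$weights), 1)

  expect_error(weight_vector(c(glucose = 0.7, lactate = 0.7)), "sum to 1")
})

test_that("MIC is 1 on noiseless functional data and monotone-invariant", {
  x <- seq(0, 1, length.out = 100)
  expect_equal(mic(x, x), 1)
  expect_equal(mic(x, x^3), mic(x, x), tolerance = 0.05)
  # symmetry
  set.seed(3)
  a <- runif(60); b <- a^2 + rnorm(60, sd = 0.1)
  expect_equal(mic(a, b), mic(b, a), tolerance = 1e-12)

  expect_error(mic(rep(1, 20), runif(20)), "constant")
  expect_error(mic(runif(5), runif(5)), "at least 8")
})

test_that("MIC null distribution on independent data stays low", {
  set.seed(10)
  nulls <- replicate(50, mic(runif(200), runif(200), b_rule = "POWER_0_6"))
  expect_lt(median(nulls), 0.35)
  expect_true(all(nulls >= 0 & nulls <= 1))
})

test_that("MIC equals an exhaustive all-partitions search at small n", {
  # a light sanity slice; the full 50-case sweep runs in the acceptance suite
  mic_exact <- asNamespace("aquavital")$mic_exact
  set.seed(42)
  n_cases <- 12
  for (case in seq_len(n_cases)) {
    n <- sample(8:12, 1)
    x <- runif(n)
    y <- switch(1 + case %% 3,
                runif(n),                      # independent
                x + rnorm(n, sd = 0.3),        # linear + noise
                sin(3 * x) + rnorm(n, sd = 0.2))
    B <- sample(8:16, 1)
    expect_equal(mic_exact(x, y, B), brute_force_mic(x, y, B),
                 tolerance = 1e-9,
                 info = sprintf("case %d (n=%d, B=%d)", case, n, B))
  }
})

test_that("screening the published MIC tables selects the printed features", {
  tabs <- mic_reference_tables()
  expect_equal(screen_features(tabs$impedance, 0.9),
               c("impedance_80", "impedance_90", "impedance_100"))
  expect_equal(screen_features(tabs$phase, 0.9),
               c("phase_70", "phase_80", "phase_90"))
  # threshold 0: everything passes, order preserved
  expect_equal(screen_features(tabs$impedance, 0),
               rownames(tabs$impedance))
  # any-factor rule admits the impedance 70 kHz row (lactate 0.991)
  expect_true("impedance_70" %in%
                screen_features(tabs$impedance, 0.9, rule = "any"))
  expect_error(screen_features(tabs$impedance[0, , drop = FALSE]), "empty")
})

test_that("screening recovers the simulated coupled frequency set", {
  # the full 84 h monitoring window: a truncated run leaves the phase
  # coupling range too small for the 0.9 threshold
  hits <- vapply(1:20, function(s) {
    sim <- simulate_experiment(simulation_config(seed = s))
    gt <- sim$ground_truth
    idx <- round(seq(1, length(gt$time_h), length.out = 150))
    fm <- wbia_feature_matrix(sim$sweeps)[idx, ]
    stress <- gt$stress[idx, ]
    class(stress) <- class(gt$stress)
    mm <- mic_matrix(fm, stress, b_rule = "POWER_0_6")
    sel <- screen_features(mm, 0.9)
    want <- c(paste0("impedance_", c(70, 80, 90, 100)),
              paste0("phase_", c(70, 80, 90, 100)))
    setequal(sel, want)
  }, logical(1))
  expect_gte(sum(hits), 18)
})
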
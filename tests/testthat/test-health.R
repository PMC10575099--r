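test_that("the health score averages orientation-corrected nutrients", {
  sim <- simulate_experiment(small_sim_config(seed = 2))
  panel <- sim$ground_truth$nutrients
  # fresh fish (time 0) score 1; end-of-run fish score 0 (all series hit
  # their extremes at the run ends by monotonicity)
  expect_equal(health_score(panel, 0), 1, tolerance = 1e-9)
  expect_equal(health_score(panel, max(panel$time_h)), 0, tolerance = 1e-9)

  # two nutrients at normalized 0.8 and 0.6 average to 0.7
  t <- c(0, 1, 2)
  vals <- list(glycogen = c(10, 10 - 0.2 * 4, 6),   # normalized 1, .8, 0
               fat = c(50, 50 - 0.4 * 10, 40),      # normalized 1, .6, 0
               crude_protein = c(1, 0.7, 0),
               atp_compounds = c(1, 0.7, 0),
               ph = c(1, 0.7, 0),
               muscle_lactate = c(0, 0.3, 1))       # rising, flipped to .7
  p2 <- nutrient_panel(t, vals)
  # glycogen .8, fat .6, others .7 -> mean = (0.8 + 0.6 + 4*0.7)/6
  expect_equal(health_score(p2, 1), (0.8 + 0.6 + 4 * 0.7) / 6)
  expect_error(health_score(p2, 99), "outside")
})

test_that("total stress is the weighted sum of normalized factors", {
  w <- default_stress_weights()
  expect_equal(total_stress(list(glucose = 1, lactate = 1, cortisol = 1), w), 1)
  expect_equal(total_stress(list(glucose = 0, lactate = 0, cortisol = 0), w), 0)
  expect_equal(
    total_stress(list(glucose = 0.5, lactate = 1.0, cortisol = 0.0), w),
    0.290 * 0.5 + 0.396 * 1.0)
  # normalizer bounds are applied
  expect_equal(
    total_stress(list(glucose = 5, lactate = 10, cortisol = 100), w,
                 normalizers = list(glucose = c(0, 10), lactate = c(0, 10),
                                    cortisol = c(0, 200))),
    0.290 * 0.5 + 0.396 * 1.0 + 0.314 * 0.5)
  expect_error(total_stress(list(glucose = 1, lactate = 1), w), "missing")
  expect_error(
    total_stress(list(glucose = 1, lactate = 1, cortisol = 1), w,
                 normalizers = list(glucose = c(1, 1), lactate = c(0, 1),
                                    cortisol = c(0, 1))),
    "bounds")
})

test_that("the Z-shaped membership function satisfies its branch identities", {
  for (ab in list(c(0.019, 1), c(0.0138, 1), c(-0.2, 0.7))) {
    a <- ab[1]; b <- ab[2]
    expect_equal(zmf(a, a, b), 1)
    expect_equal(zmf(b, a, b), 0)
    expect_equal(zmf((a + b) / 2, a, b), 0.5)
    # continuity at the joints and monotone nonincreasing on a dense grid
    g <- seq(a - 0.1, b + 0.1, length.out = 2001)
    v <- zmf(g, a, b)
    expect_true(all(diff(v) <= 1e-12))
    joints <- c(a, (a + b) / 2, b)
    for (j in joints) {
      expect_lte(abs(zmf(j - 1e-9, a, b) - zmf(j + 1e-9, a, b)), 1e-6)
    }
  }
  expect_equal(zmf(0.5095, 0.019, 1), 0.5, tolerance = 1e-9)
  expect_equal(zmf(0.25, 0, 1), 0.875)
})

test_that("envelope fitting recovers the ZMF coefficient", {
  s <- seq(0.02, 0.99, length.out = 40)
  fit <- fit_zmf_envelope(s, zmf(s, 0.2, 1), b_fixed = 1)
  expect_equal(fit$a, 0.2, tolerance = 1e-6)

  # symmetric score jitter of +-0.05 on points from the steep transition
  # region (the flat ZMF tails make enclosure ill-posed under vertical
  # jitter): midpoint lands within (0.1, 0.3)
  s_mid <- seq(0.45, 0.75, length.out = 40)
  for (seed in 1:20) {
    set.seed(seed)
    jit <- pmin(pmax(zmf(s_mid, 0.2, 1) + runif(length(s_mid), -0.05, 0.05), 0), 1)
    f <- fit_zmf_envelope(s_mid, jit, b_fixed = 1)
    expect_gt(f$a, 0.1)
    expect_lt(f$a, 0.3)
  }

  # single point at s = b with score 0: any curve encloses; warn + midpoint
  expect_warning(deg <- fit_zmf_envelope(1, 0, b_fixed = 1), "midpoint")
  expect_true(is.finite(deg$a))
})

test_that("classification follows the zone threshold tables", {
  expect_equal(as.character(classify_health(0.30, level_thresholds("ZONE_1_3"))), "SLL")
  expect_equal(as.character(classify_health(0.70, level_thresholds("ZONE_1_3"))), "BLL")
  # boundary is left-closed
  expect_equal(as.character(classify_health(0.368, level_thresholds("ZONE_3_6"))), "MLL")
  expect_equal(as.character(classify_health(0.406, level_thresholds("ZONE_1_3"))), "MLL")
  expect_equal(
    as.character(classify_health(c(0, 0.5, 0.79, 0.99), level_thresholds("ZONE_1_3"))),
    c("SLL", "MLL", "WLL", "DS"))
  # monotone: higher stress never maps to a healthier level
  g <- seq(0, 1, by = 0.001)
  lv <- as.integer(classify_health(g, level_thresholds("ZONE_3_6")))
  expect_true(all(diff(lv) >= 0))
})

test_that("assessed health levels never improve over a monotone stress run", {
  for (seed in 1:20) {
    sim <- simulate_experiment(small_sim_config(
      seed = seed, noise_sd = 0, gross_error_rate = 0))
    gt <- sim$ground_truth
    a <- assess_health(gt$time_h, gt$total_stress01, zone = "ZONE_1_3")
    lv <- as.integer(a$level)
    expect_true(all(diff(lv) >= 0))
    expect_true(all(a$hq >= 0 & a$hq <= 1))
    expect_true(all(diff(a$hq) <= 1e-12))
  }
})

test_that("the near-death point follows the survival stopping rule", {
  sched <- data.frame(checkpoint_hour = c(60, 72, 78, 84),
                      cumulative_deaths = c(2, 5, 8, 11))
  nd <- near_death_point(sched, 25)
  expect_equal(nd$hour, 84)
  expect_equal(nd$survival_rate, 0.56)

  expect_null(near_death_point(
    data.frame(checkpoint_hour = 60, cumulative_deaths = 0), 25))
  # threshold 1: the first death crosses immediately
  first <- near_death_point(sched, 25, survival_threshold = 1)
  expect_equal(first$hour, 60)
  expect_error(near_death_point(
    data.frame(checkpoint_hour = c(1, 2), cumulative_deaths = c(3, 2)), 25),
    "malformed")
})
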
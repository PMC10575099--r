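test_that("an isolated gross error is removed and the filter is idempotent", {
  x <- c(1.0, 1.1, 0.9, 1.05, 0.95, 10.0)
  flt <- romanovsky_filter(x)
  expect_equal(flt$removed_indices, 6L)
  expect_equal(flt$cleaned, x[1:5])

  again <- romanovsky_filter(flt$cleaned)
  expect_length(again$removed_indices, 0)

  expect_equal(romanovsky_filter(rep(2, 5))$removed_indices, integer(0))
  expect_error(romanovsky_filter(c(1, 2, 3)), "insufficient data")
})

test_that("clean Gaussian series lose at most 2*alpha of their samples", {
  fracs <- vapply(1:100, function(s) {
    set.seed(s)
    length(romanovsky_filter(rnorm(200))$removed_indices) / 200
  }, numeric(1))
  expect_lte(mean(fracs), 2 * 0.05)
})

test_that("Savitzky-Golay reproduces low-order polynomials and is linear", {
  t <- seq(-3, 3, length.out = 21)
  quad <- 2 + 0.5 * t - 1.3 * t^2
  expect_equal(savgol_smooth(quad, w = 2, poly_order = 2), quad,
               tolerance = 1e-10)
  expect_equal(savgol_smooth(c(1, 2, 3, 4, 5), w = 2, poly_order = 2),
               c(1, 2, 3, 4, 5))

  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  lin <- savgol_smooth(2 * x - 3 * y, w = 3, poly_order = 2)
  expect_equal(lin, 2 * savgol_smooth(x, 3, 2) - 3 * savgol_smooth(y, 3, 2))

  expect_equal(savgol_smooth(rep(7, 15), w = 5, poly_order = 3), rep(7, 15))
  expect_error(savgol_smooth(1:5, w = 5, poly_order = 3), "window longer")
})

test_that("interior SG coefficients match the analytic least-squares weights", {
  expect_equal(savgol_coefficients(2, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  # weights of any window/order sum to 1 (constant preservation)
  expect_equal(sum(savgol_coefficients(5, 3)), 1, tolerance = 1e-12)
})

test_that("natural spline completion is exact at knots and linear data", {
  t <- c(0, 2, 5, 9)
  line <- 3 - 0.5 * t
  q <- seq(0, 9, by = 0.25)
  expect_equal(spline_complete(t, line, q), 3 - 0.5 * q, tolerance = 1e-10)
  expect_equal(spline_complete(t, line, t), line)

  # cubic data: natural end conditions give a close but inexact interior
  # value (hand tridiagonal solve: M = (0, 36/5, 84/5, 0) -> 3.15 at t=1.5)
  val <- spline_complete(0:3, (0:3)^3, 1.5)
  expect_equal(val, 3.15, tolerance = 1e-9)
  expect_lt(abs(val - 3.375) / 3.375, 0.10)
  expect_false(isTRUE(all.equal(val, 3.375)))

  expect_error(spline_complete(0:3, (0:3)^3, 3.5), "extrapolation")
  expect_error(spline_complete(c(0, 1), c(0, 1), 0.5), "3 checkpoints")
})

test_that("gross-error recovery on simulated runs is near-perfect", {
  # recall >= 0.95 and false-positive rate <= 0.05 (a 12-seed slice; the
  # 50-seed version runs in the acceptance suite)
  stats <- sapply(1:12, function(s) {
    sim <- simulate_experiment(small_sim_config(seed = s))
    pp <- preprocess_sweeps(sim$sweeps)
    truth <- sim$ground_truth$outlier_positions
    times <- sort(unique(sim$sweeps$timestamp))
    truth_key <- paste(format(times[truth$time_index]),
                       truth$frequency_khz, truth$channel)
    rem_key <- paste(format(pp$removed$timestamp), pp$removed$frequency_khz,
                     sub("_ohm", "", pp$removed$channel))
    c(recall = mean(truth_key %in% rem_key),
      fp = sum(!(rem_key %in% truth_key)) /
        (2 * nrow(sim$sweeps) - nrow(truth)))
  })
  expect_gte(mean(stats["recall", ]), 0.95)
  expect_lte(mean(stats["fp", ]), 0.05)
})

test_that("preprocessing smooths channels without biasing them", {
  sim <- simulate_experiment(small_sim_config(seed = 3))
  pp <- preprocess_sweeps(sim$sweeps)
  raw <- sim$sweeps$r_ohm
  cln <- pp$frames$r_ohm
  expect_equal(mean(cln), mean(raw), tolerance = 1e-3)
  # smoothing reduces high-frequency energy
  expect_lt(sd(diff(cln)), sd(diff(raw)))
})
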
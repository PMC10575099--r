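# Frozen end-to-end simulation experiments used by the validation suite and
# the acceptance script.  Conditions: a 24 h run sampled every 10 min with
# hourly biomarker checkpoints; the forecast target is the spline-completed
# lactate series (a logistic trend plus a smooth autocorrelated deviation
# from the noisy checkpoints); inputs are the preprocessed coupled
# impedance/phase channels plus temperature; models are trained at reduced
# size (1 recurrent layer, hidden 12/8, 25 epochs) so that many seeds fit
# in a desk-scale budget.

ranking_experiment_inputs <- function(seed) {
  sim <- simulate_experiment(simulation_config(
    seed = seed, duration_hours = 24, sample_interval_minutes = 10,
    checkpoint_hours = 0:24))
  pp <- preprocess_sweeps(sim$sweeps)
  fm <- wbia_feature_matrix(pp$frames)
  sel <- c(paste0("impedance_", c(70, 80, 90, 100)),
           paste0("phase_", c(70, 80, 90, 100)), "temperature")
  sub <- fm[, sel, drop = FALSE]
  attr(sub, "time_h") <- attr(fm, "time_h")
  dense <- complete_stress_series(sim$stress, attr(fm, "time_h"))
  list(sim = sim, features = sub, target = dense$lactate)
}

experiment_config <- function(seed, epochs = 25) {
  hybrid_config(epochs = epochs, patience = epochs, lstm_hidden = 12,
                lstm_layers = 1, bigru_hidden = 8, bigru_layers = 1,
                cnn_channels = 6, seed = seed)
}

# Held-out RMSE of the requested architectures on one simulated run.
ranking_experiment <- function(seed, models = c("cnn_lstm_bigru", "lstm"),
                               epochs = 25) {
  inp <- ranking_experiment_inputs(seed)
  win <- build_windows(inp$features, inp$target, window_length = 15,
                       horizon_steps = 1)
  cfg <- experiment_config(seed, epochs)
  vapply(models, function(m) {
    fit <- if (m == "cnn_lstm_bigru") train_hybrid(win, cfg, "lactate")
           else train_baseline(win, m, cfg, "lactate")
    fit$test$rmse
  }, numeric(1))
}

# Fraction of held-out points whose 95% band covers the noiseless
# ground-truth lactate trajectory on one simulated run.
coverage_experiment <- function(seed, epochs = 25) {
  inp <- ranking_experiment_inputs(seed)
  win <- build_windows(inp$features, inp$target, window_length = 15,
                       horizon_steps = 1)
  m <- train_hybrid(win, experiment_config(seed, epochs), "lactate")
  gt <- inp$sim$ground_truth
  gt_at <- gt$stress$lactate[match(round(m$test$time_h, 6),
                                   round(gt$time_h, 6))]
  mean(abs(m$test$pred - gt_at) <= 1.96 * m$resid_sd)
}
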
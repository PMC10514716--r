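test_that("trial averaging returns the input for identical sweeps and enforces the contract", {
  m <- synapse_model(noise_sd = 0)
  s <- simulate_epsc_train(m, 0.05, seed = 1)
  avg <- average_trials(list(s, s, s))
  expect_equal(avg$current, s$current)
  expect_error(average_trials(list(s, s)), "3-7")
  expect_warning(average_trials(list(s, s), permissive = TRUE), "3-7")
  s2 <- simulate_epsc_train(m, 0.06, seed = 1, sweep_duration = 0.2)
  expect_error(average_trials(list(s, s, s2)), "onsets")
})

test_that("averaging 7 trials shrinks trace noise by sqrt(7)", {
  m <- synapse_model(base_amplitude = 50, noise_sd = 5)
  # empirical noise sd over 100 simulated repetitions, measured on the
  # pre-pulse baseline where the clean trace is flat
  set.seed(42)
  sd1 <- sd7 <- numeric(100)
  base_idx <- 1:400                      # 40 ms before the pulse at 50 ms
  for (k in 1:100) {
    sw <- lapply(1:7, function(i)
      simulate_epsc_train(m, 0.05, seed = 7000 + 7 * k + i,
                          sweep_duration = 0.1))
    sd1[k] <- sd(sw[[1]]$current[base_idx])
    sd7[k] <- sd(average_trials(sw)$current[base_idx])
  }
  expect_equal(mean(sd1) / mean(sd7), sqrt(7), tolerance = 0.05)
})

test_that("noise-free peak-to-trough amplitudes match generator ground truth", {
  m <- synapse_model(noise_sd = 0)
  s1 <- simulate_epsc_train(m, 0.05)
  expect_equal(measure_pulse_amplitudes(s1), 100, tolerance = 0.005 * 100)
  # overlapping decays at 10 Hz: within 1% of the baseline-referenced truth
  tr <- simulate_epsc_train(m, 0.05 + seq(0, 0.9, 0.1))
  a <- measure_pulse_amplitudes(tr)
  gt <- tr$ground_truth$amplitudes
  expect_lt(max(abs(a - gt) / gt), 0.01)
})

test_that("flat traces yield zero amplitudes and truncated windows are rejected", {
  flat <- make_sweep(rep(-50, 3000), 10000, c(0.05, 0.15))
  expect_equal(measure_pulse_amplitudes(flat), c(0, 0))
  late <- make_sweep(rep(-50, 600), 10000, 0.05)  # window would end at 0.15 s
  expect_error(measure_pulse_amplitudes(late), "window")
})

test_that("decay tau is recovered from a pure exponential to 0.1 ms", {
  fs <- 10000
  tt <- (0:1999) / fs
  cur <- rep(-50, 2000)
  post <- tt >= 0.05
  cur[post] <- -50 - 80 * exp(-(tt[post] - 0.05) / 0.015)
  s <- make_sweep(cur, fs, 0.05)
  fit <- fit_decay_tau(s)
  expect_true(fit$ok)
  expect_equal(fit$tau, 15, tolerance = 0.1 / 15)
})

test_that("decay tau on a slow-decay kernel is within 5% of tau_decay", {
  m <- synapse_model(tau_rise = 1, tau_decay = 40, noise_sd = 0)
  s <- simulate_epsc_train(m, 0.02, sweep_duration = 0.35)
  fit <- fit_decay_tau(s, max_window = 0.3)
  expect_true(fit$ok)
  expect_equal(fit$tau, 40, tolerance = 0.05)
})

test_that("flat segments are flagged rather than fitted", {
  flat <- make_sweep(rep(-50, 2000), 10000, 0.05)
  fit <- fit_decay_tau(flat)
  expect_false(fit$ok)
  expect_match(fit$reason, "peak")
})

test_that("normalization schemes compute the documented ratios", {
  test <- c(75, 60); control <- c(100, 80)
  expect_equal(normalize_train(test, control, "pointwise_vs_control")$values,
               c(0.75, 0.75))
  expect_equal(normalize_train(test, control, "train_vs_first_control")$values,
               c(0.75, 0.60))
  expect_equal(normalize_train(test, control, "first_vs_first")$values, 0.75)
  expect_equal(normalize_train(test, control, "mean_vs_mean")$values, 0.75)
  expect_equal(normalize_train(test, control, "within_train")$values, c(1, 0.8))
  # control against itself is the constant 1 under the pointwise scheme
  expect_equal(normalize_train(control, control, "pointwise_vs_control")$values,
               c(1, 1))
  expect_equal(normalize_train(control, control, "first_vs_first")$values, 1)
  expect_equal(normalize_train(control, control, "mean_vs_mean")$values, 1)
  # first_vs_first equals element 1 of train_vs_first_control
  expect_equal(normalize_train(test, control, "first_vs_first")$values,
               normalize_train(test, control, "train_vs_first_control")$values[1])
  # zero divisor flagged per element
  z <- normalize_train(c(1, 2), c(0, 2), "pointwise_vs_control")
  expect_true(z$flagged[1]); expect_false(z$flagged[2])
  expect_true(is.na(z$values[1]))
})

test_that("paired-pulse and steady-state ratios follow their definitions", {
  expect_equal(paired_pulse_ratio(c(100, 80))$ppr, 0.8)
  expect_equal(paired_pulse_ratio(c(50, 50))$ppr, 1)
  expect_true(paired_pulse_ratio(c(0, 10))$flagged)
  expect_error(paired_pulse_ratio(100), "2 pulses")
  expect_equal(steady_state_ratio(c(100, 60, 50, 50, 50), 3), 0.5)
  expect_equal(steady_state_ratio(rep(70, 6)), 1)
  expect_error(steady_state_ratio(c(1, 2, 3), 3), "longer")
  # measured steady state of a simulated depletion train matches the
  # closed-form fixed point within 2%
  m <- synapse_model(release_fraction = 0.5, tau_recovery = 200, noise_sd = 0)
  tr <- simulate_epsc_train(m, 0.05 + seq(0, by = 0.1, length.out = 20))
  ss <- steady_state_ratio(measure_pulse_amplitudes(tr), 3)
  expect_equal(ss, closed_form_rss(0.5, 200, 100), tolerance = 0.02)
})

test_that("measured depression is monotone in stimulus rate", {
  m <- synapse_model(noise_sd = 0)
  ss <- sapply(c(5, 10), function(rate) {
    tr <- simulate_epsc_train(m, 0.05 + seq(0, by = 1 / rate, length.out = 10))
    steady_state_ratio(measure_pulse_amplitudes(tr), 3)
  })
  expect_lte(ss[2], ss[1])
})

test_that("series-resistance QC applies the absolute and relative rules", {
  expect_true(qc_series_resistance(rep(25, 5))$pass)
  bad_abs <- qc_series_resistance(c(25, 25, 31, 25, 25))
  expect_false(bad_abs$pass)
  expect_match(bad_abs$reason, "30")
  bad_rel <- qc_series_resistance(c(20, 21, 22, 23, 24))
  expect_false(bad_rel$pass)
  expect_match(bad_rel$reason, "15%")
  expect_error(qc_series_resistance(c(20, -1)), "positive")
})

test_that("noiseless simulate-measure round trip recovers all train metrics within 1%", {
  m <- synapse_model(release_fraction = 0.4, tau_recovery = 200, noise_sd = 0)
  tr <- simulate_epsc_train(m, 0.05 + seq(0, 0.9, 0.1))
  met <- epsc_train_metrics(average_trials(list(tr, tr, tr)))
  gt <- tr$ground_truth$amplitudes
  expect_lt(max(abs(met$amplitudes - gt) / gt), 0.01)
  expect_equal(met$ppr, gt[2] / gt[1], tolerance = 0.01)
  expect_equal(met$steady_state, mean(tail(gt, 3)) / gt[1], tolerance = 0.01)
  expect_true(met$qc$pass)
})
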
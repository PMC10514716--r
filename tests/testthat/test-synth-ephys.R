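test_that("EPSC kernel vanishes at onset and peaks at the analytic peak time", {
  expect_equal(epsc_kernel(0, 1, 15, 100), 0)
  # oracle: numerically maximize the unnormalized kernel
  tr <- 1; td <- 15
  t_star <- tr * td / (td - tr) * log(td / tr)
  opt <- optimize(function(t) exp(-t / td) - exp(-t / tr),
                  c(0, 100), maximum = TRUE)
  expect_equal(t_star, opt$maximum, tolerance = 1e-4)
  expect_equal(epsc_kernel(t_star, tr, td, 100), 100, tolerance = 1e-9)
  expect_lt(max(epsc_kernel(seq(0, 100, 0.01), tr, td, 100)), 100 + 1e-6)
})

test_that("kernel decays with tau_decay in the fast-rise limit", {
  td <- 15
  t <- seq(20, 80, 0.1)
  k <- epsc_kernel(t, 1e-5, td, 1)
  fit <- stats::lm(log(k) ~ t)
  expect_equal(-1 / coef(fit)[["t"]], td, tolerance = 1e-3)
})

test_that("degenerate kernel time constants are rejected", {
  expect_error(epsc_kernel(1, 15, 15), "tau_rise")
  expect_error(synapse_model(tau_rise = 20, tau_decay = 15), "tau_rise")
})

test_that("the depletion recursion converges to its closed-form fixed point", {
  for (U in c(0.2, 0.5, 0.8)) for (tau in c(100, 200, 500)) {
    for (rate in c(5, 10)) {
      dt <- 1 / rate
      R <- depletion_profile(seq(0, by = dt, length.out = 200), U, tau)
      expect_equal(R[200], closed_form_rss(U, tau, dt * 1000), tolerance = 1e-8)
    }
  }
})

test_that("depression is absent as U approaches 0 and monotone in rate", {
  on <- seq(0, 0.9, by = 0.1)
  expect_equal(depletion_profile(on, 1e-9, 200), rep(1, 10), tolerance = 1e-6)
  for (U in c(0.2, 0.5, 0.8)) for (tau in c(50, 200, 800)) {
    r5 <- closed_form_rss(U, tau, 200)
    r10 <- closed_form_rss(U, tau, 100)
    expect_lte(r10, r5)
  }
})

test_that("simulated trains carry exact noiseless ground truth", {
  m <- synapse_model(base_amplitude = 100, noise_sd = 0)
  s1 <- simulate_epsc_train(m, 0.05)
  expect_equal(s1$ground_truth$amplitudes, 100)
  s2 <- simulate_epsc_train(m, 0.05, condition = "chelator")
  expect_equal(s2$ground_truth$amplitudes, 75)
  # 10 Hz steady state matches the closed form
  m2 <- synapse_model(release_fraction = 0.5, tau_recovery = 200, noise_sd = 0)
  tr <- simulate_epsc_train(m2, 0.05 + seq(0, by = 0.1, length.out = 40))
  rss <- closed_form_rss(0.5, 200, 100)
  expect_equal(tr$ground_truth$depletion[40], rss, tolerance = 1e-4)
  expect_error(simulate_epsc_train(m, 0.05, condition = "nonsense"), "condition")
})

test_that("simulated sweeps are reproducible and inward-going", {
  m <- synapse_model()
  a <- simulate_epsc_train(m, c(0.05, 0.15), seed = 7)
  b <- simulate_epsc_train(m, c(0.05, 0.15), seed = 7)
  expect_identical(a$current, b$current)
  expect_lt(min(a$current), m$holding_current)  # deflection is negative
})

test_that("series-resistance logs hit the requested drift exactly", {
  expect_equal(simulate_rs_log(25, 0, 5), rep(25, 5))
  log2 <- simulate_rs_log(25, 0.20, 5)
  expect_equal(log2[5], 30)
  expect_equal(max(abs(log2 - log2[1]) / log2[1]), 0.20)
  expect_false(qc_series_resistance(simulate_rs_log(32, 0, 5))$pass)
  expect_error(simulate_rs_log(-1, 0, 5), "positive")
  expect_error(simulate_rs_log(25, 0, 1), "n_checks")
})

test_that("sweeps round-trip through the text format with ground truth", {
  m <- synapse_model()
  s <- simulate_epsc_train(m, c(0.05, 0.25), seed = 3)
  path <- file.path(tempdir(), "sweep.tsv")
  write_sweep(s, path)
  back <- read_sweep(path)
  expect_equal(back$current, s$current, tolerance = 1e-6)
  expect_equal(back$pulse_onsets, s$pulse_onsets)
  expect_equal(back$condition, s$condition)
  expect_equal(back$ground_truth$amplitudes, s$ground_truth$amplitudes,
               tolerance = 1e-6)
})
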
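test_that("delta-F/F normalizes to the 1-s pre-onset baseline", {
  v <- rep(100, 20)
  d <- compute_dff(v, 11, 5)
  expect_equal(d$f0, 100)
  expect_true(all(d$dff == 0))
  v[12] <- 110
  expect_equal(compute_dff(v, 11, 5)$dff[2], 0.10)
  expect_true(compute_dff(rep(0, 20), 11, 5)$flagged)
  expect_error(compute_dff(v, 3, 5), "pre-onset")
})

test_that("Z-scoring is exact under the population convention", {
  # hand computation for (0,0,0,1): mean 0.25, population sd
  # sqrt(0.1875) = 0.4330, so z = (-0.25, -0.25, -0.25, 0.75) / 0.4330
  z <- zscore_trace(c(0, 0, 0, 1))
  expect_equal(z$z, c(-0.25, -0.25, -0.25, 0.75) / sqrt(0.1875))
  x <- rnorm(50)
  zz <- zscore_trace(x)$z
  expect_equal(mean(zz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zz^2)), 1, tolerance = 1e-12)
  expect_true(zscore_trace(rep(3, 10))$flagged)
  # sample convention: sd 0.5 gives the (-0.5, -0.5, -0.5, 1.5) pattern
  zs <- zscore_trace(c(0, 0, 0, 1), convention = "sample")
  expect_equal(zs$z, c(-0.5, -0.5, -0.5, 1.5))
})

test_that("response detection needs two consecutive supra-threshold frames", {
  fr <- 5
  z <- c(rep(0, 5), 0.7, 0.7, 0, 0, 0, rep(0, 5))
  expect_true(detect_response(z, 6, fr)$responsive)
  z2 <- c(rep(0, 5), 0.2, 5, 0.2, 0, 0, rep(0, 5))
  det2 <- detect_response(z2, 6, fr)
  expect_false(det2$responsive)
  expect_equal(det2$peak_z, 5)
  z3 <- rep(0.6, 15)
  expect_false(detect_response(z3, 6, fr)$responsive)  # strict inequality
  expect_error(detect_response(z, 13, fr), "window")
})

test_that("the 2-D Butterworth filter passes DC and attenuates high frequencies", {
  img <- matrix(5, 32, 32)
  expect_equal(butterworth2d(img), img, tolerance = 1e-9)
  checker <- outer(1:32, 1:32, function(i, j) (-1)^(i + j))
  filt <- butterworth2d(checker, cutoff = 0.1, order = 2)
  expect_lt(max(abs(filt)), 0.05 * max(abs(checker)))
})

test_that("the wide-field map averages exactly 10 frames at 20 Hz", {
  regions <- list(list(center = c(40, 40), radius = 5, amplitude = 0.1))
  mov <- simulate_widefield_movie(regions, onsets = 1.5, tone_duration = 0.5,
                                  total_s = 5, dims = c(80, 80), noise_sd = 0)
  map <- widefield_map(mov)
  expect_equal(map$n_avg_frames, 10L)
  expect_equal(round(0.5 * mov$frame_rate), 10)
  # truncating the movie below 10 post-offset frames must fail
  short <- mov
  short$frames <- mov$frames[, , 1:45]   # offset frame is 41
  expect_error(widefield_map(short), "10")
})

test_that("a stimulus-free map yields no regions and small blobs are size-filtered", {
  regions <- list(list(center = c(40, 40), radius = 3, amplitude = 0.1))
  mov <- simulate_widefield_movie(regions, dims = c(80, 80), noise_sd = 0)
  map <- widefield_map(mov)
  expect_equal(nrow(detect_regions(map, min_area_px = 10000)), 0L)
  flat <- simulate_widefield_movie(
    list(list(center = c(40, 40), radius = 3, amplitude = 0)),
    dims = c(80, 80), noise_sd = 0)
  expect_equal(nrow(detect_regions(widefield_map(flat))), 0L)
})

test_that("the noise-free pipeline reproduces the generator mask and metrics exactly", {
  blk <- default_block()
  for (thr in c(40, 50)) {
    m <- clean_rf_model(threshold_true = thr)
    roi <- simulate_roi_traces(m, blk, seed = 21)
    tm <- tuning_metrics(roi)
    gt <- roi$ground_truth
    expect_equal(unname(tm$surface$responsive), unname(gt$mask))
    expect_equal(tm$bf, gt$bf)
    expect_equal(tm$threshold, gt$threshold)
    expect_equal(tm$q20, gt$q20)
    expect_true(tm$is_sound_responsive)
  }
  # silent neuron: empty mask, all metrics flagged
  silent <- simulate_roi_traces(clean_rf_model(peak_dff = 0), blk, seed = 22)
  tms <- tuning_metrics(silent)
  expect_false(tms$is_sound_responsive)
  expect_true(is.na(tms$bf) && is.na(tms$threshold) && is.na(tms$q20))
})

test_that("raising the detection threshold never grows the responsive mask", {
  blk <- default_block()
  m <- receptive_field_model(noise_sd = 0.3)
  roi <- simulate_roi_traces(m, blk, seed = 31)
  masks <- lapply(c(0.4, 0.6, 1.0, 1.5), function(th)
    build_tuning_surface(roi, z_thresh = th)$responsive)
  for (i in 1:3)
    expect_true(all(masks[[i]][masks[[i + 1]]]))
  # Q20 is non-increasing in the threshold for a noise-free rectangular field
  roi0 <- simulate_roi_traces(clean_rf_model(), blk, seed = 32)
  q <- sapply(c(0.4, 0.6, 1.0), function(th) {
    s <- build_tuning_surface(roi0, z_thresh = th)
    q20_bandwidth(s)$q20
  })
  expect_true(all(diff(q) <= 0))
})

test_that("best frequency breaks exact ties toward the lower frequency", {
  freqs <- c(5000, 10000, 20000); lv <- c(50, 70)
  pz <- matrix(c(1, 2, 2, 1, 1, 1), 2, 3, byrow = TRUE)
  resp <- matrix(TRUE, 2, 3)
  s <- make_surface(pz, resp, freqs, lv)
  expect_equal(best_frequency(s)$bf, 10000)
  # no responses: flagged
  s2 <- make_surface(pz, matrix(FALSE, 2, 3), freqs, lv)
  expect_true(best_frequency(s2)$flagged)
})

test_that("threshold and Q20 follow their definitions on crafted surfaces", {
  freqs <- c(5000, 10000, 20000, 40000); lv <- c(40, 50, 60, 70, 80)
  resp <- matrix(FALSE, 5, 4)
  resp[3:5, 2] <- TRUE                      # responses only at 60-80 dB
  pz <- matrix(1, 5, 4)
  s <- make_surface(pz, resp, freqs, lv)
  expect_equal(response_threshold(s)$threshold, 60)
  # at threshold + 20 (80 dB) only 10 kHz responds: Q20 = 0
  expect_equal(q20_bandwidth(s)$q20, 0)
  # responsive 10-20 kHz at threshold + 20 gives one octave
  resp2 <- resp; resp2[5, 3] <- TRUE
  expect_equal(q20_bandwidth(make_surface(pz, resp2, freqs, lv))$q20, 1)
  # responsive 5-40 kHz gives three octaves
  resp3 <- resp; resp3[5, ] <- TRUE
  expect_equal(q20_bandwidth(make_surface(pz, resp3, freqs, lv))$q20, 3)
  # threshold 70 dB: threshold + 20 not tested, neuron excluded
  resp4 <- matrix(FALSE, 5, 4); resp4[4:5, 2] <- TRUE
  expect_true(q20_bandwidth(make_surface(pz, resp4, freqs, lv))$flagged)
})

test_that("d-prime matches a direct reimplementation of its formula", {
  blk <- default_block()
  m <- receptive_field_model(noise_sd = 0.2)
  roi <- simulate_roi_traces(m, blk, seed = 41)
  surf <- build_tuning_surface(roi)
  dp <- dprime_neuron(surf)
  expect_false(dp$flagged)
  # brute force: locate the BF cell, pull its repeat windows, apply the formula
  pz <- surf$peak_z; pz[!surf$responsive] <- -Inf
  hit <- which(pz == max(pz), arr.ind = TRUE)
  li <- hit[1, 1]
  fi <- which(surf$frequencies == surf$frequencies[min(hit[, 2])])[1]
  ev <- surf$repeat_windows$evoked[li, fi, ]
  bl <- surf$repeat_windows$baseline[li, fi, ]
  ref <- (mean(ev) - mean(bl)) / sqrt((var(ev) + var(bl)) / 2)
  expect_equal(dp$dprime, ref)
  expect_gt(dp$dprime, 0)
})

test_that("d-prime is zero for evoked identical to baseline", {
  surf <- make_surface(matrix(1, 1, 1), matrix(TRUE, 1, 1), 10000, 60)
  w <- array(rep(c(0.1, 0.3, 0.2, 0.25, 0.15), each = 1), c(1, 1, 5))
  surf$repeat_windows <- list(evoked = w, baseline = w)
  expect_equal(dprime_neuron(surf)$dprime, 0)
})

test_that("top-fraction selection keeps ceil(fraction * n), at least one", {
  expect_length(select_top_fraction(rnorm(10)), 2L)
  expect_length(select_top_fraction(rnorm(100)), 20L)
  expect_length(select_top_fraction(rnorm(3)), 1L)
  expect_length(select_top_fraction(numeric()), 0L)
  # ties at the cutoff: earlier input wins
  expect_equal(select_top_fraction(c(1, 2, 2, 2, 0), fraction = 0.4), c(2, 3))
  # the selected indices carry the largest values
  d <- c(0.1, 3, 0.5, 2.5, 1, 0.2, 0.3, 4, 0.4, 0.6)
  expect_setequal(select_top_fraction(d), c(2, 8))
})
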
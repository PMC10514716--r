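test_that("ground-truth Q20 is exact by construction for rectangular fields", {
  blk <- default_block()
  m <- clean_rf_model()   # threshold 50, bandwidth 1 octave at threshold + 20
  gt <- rf_ground_truth(m, blk$frequencies, blk$levels)
  expect_equal(gt$bf, 10000)
  expect_equal(gt$threshold, 50)
  expect_equal(gt$q20, 1.0)
  # condition gain scales the true bandwidth multiplicatively
  gt2 <- rf_ground_truth(m, blk$frequencies, blk$levels, condition = "zx1")
  expect_equal(gt2$q20, 1.25)
  expect_true(all(gt2$mask[gt$mask]))    # widened mask contains the original
})

test_that("a flat model is silent everywhere", {
  blk <- default_block()
  m <- clean_rf_model(peak_dff = 0)
  gt <- rf_ground_truth(m, blk$frequencies, blk$levels)
  expect_false(any(gt$mask))
  expect_true(is.na(gt$bf))
  roi <- simulate_roi_traces(m, blk, seed = 1)
  expect_equal(unique(as.vector(roi$values)), 1)
})

test_that("the GCaMP kernel peaks within 1 s of onset", {
  t <- seq(0, 3, 0.001)
  k <- gcamp_kernel(t)
  expect_lt(t[which.max(k)], 1)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_equal(gcamp_kernel(-0.5), 0)
})

test_that("ROI trace simulation is seeded and validates inputs", {
  blk <- default_block()
  m <- receptive_field_model()
  expect_error(simulate_roi_traces(m, blk, n_repeats = 0), "n_repeats")
  a <- simulate_roi_traces(m, blk, seed = 5)
  b <- simulate_roi_traces(m, blk, seed = 5)
  expect_identical(a$values, b$values)
  # per-repeat orders are re-drawn but cover the same stimulus set
  o1 <- a$repeats[[1]][, c("frequency_hz", "level_db")]
  o2 <- a$repeats[[2]][, c("frequency_hz", "level_db")]
  expect_false(identical(o1, o2))
  expect_setequal(paste(o1[[1]], o1[[2]]), paste(o2[[1]], o2[[2]]))
})

test_that("ROI traces round-trip through the text format", {
  blk <- default_block()
  roi <- simulate_roi_traces(receptive_field_model(), blk, n_repeats = 2,
                             seed = 9)
  path <- file.path(tempdir(), "roi.tsv")
  write_roi_trace(roi, path)
  back <- read_roi_trace(path)
  expect_equal(back$values, roi$values, tolerance = 1e-6)
  expect_equal(back$ground_truth$mask, unname(roi$ground_truth$mask))
  expect_equal(back$repeats[[1]]$onset_frame, roi$repeats[[1]]$onset_frame)
})

test_that("wide-field blobs appear at their ground-truth centres", {
  regions <- list(list(center = c(50, 60), radius = 6, amplitude = 0.1),
                  list(center = c(100, 150), radius = 6, amplitude = 0.08))
  mov <- simulate_widefield_movie(regions, noise_sd = 0, seed = 1)
  expect_equal(dim(mov$frames)[1:2], c(150, 200))
  expect_equal(mov$frame_rate, 20)
  map <- widefield_map(mov)
  # oracle: blobs are far apart, so each local maximum is the analytic centre
  peak <- which(map$dff_image == max(map$dff_image), arr.ind = TRUE)
  expect_lte(max(abs(peak[1, ] - c(50, 60))), 1)
  det <- detect_regions(map)
  expect_equal(nrow(det), 2L)
  ord <- order(det$centroid_row)
  expect_lt(abs(det$centroid_row[ord[1]] - 50), 2)
  expect_lt(abs(det$centroid_col[ord[1]] - 60), 2)
  expect_lt(abs(det$centroid_row[ord[2]] - 100), 2)
  expect_lt(abs(det$centroid_col[ord[2]] - 150), 2)
})

test_that("zero-amplitude regions give a flat map and out-of-frame centres fail", {
  regions <- list(list(center = c(50, 60), radius = 6, amplitude = 0))
  mov <- simulate_widefield_movie(regions, noise_sd = 0, seed = 1)
  map <- widefield_map(mov)
  expect_lt(max(abs(map$dff_image)), 1e-9)
  expect_error(simulate_widefield_movie(
    list(list(center = c(500, 60), radius = 6, amplitude = 0.1))), "frame")
})
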
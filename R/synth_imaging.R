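#' GCaMP response kernel
#'
#' Peak-normalised difference of exponentials used as the calcium-indicator
#' impulse response.  With the defaults (rise 0.1 s, decay 1.0 s) the kernel
#' peaks about 0.26 s after onset, well inside the 1-s quantification window.
#'
#' @param t time since stimulus onset, s (negative values give 0).
#' @param tau_rise,tau_decay time constants, s (`tau_rise < tau_decay`).
#' @return kernel values peaking at 1.
#' @export
gcamp_kernel <- function(t, tau_rise = 0.1, tau_decay = 1.0) {
  stop_if(tau_rise >= tau_decay, "tau_rise must be smaller than tau_decay")
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  k_max <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / k_max
  out
}

#' Frequency-intensity receptive-field model with known ground truth
#'
#' The responsive region is rectangular in log-frequency at each level:
#' stimulus (f, l) is responsive iff `l >= threshold_true` and
#' `|log2(f / bf_true)| <= bandwidth(l) * gain(condition) / 2`, where the
#' bandwidth grows linearly with level above threshold (a V-shaped field) and
#' the condition gain multiplies it.  Within the band the injected response
#' amplitude is tapered (triangular in octave distance from BF) and grows
#' with level, so the noise-free global maximum sits exactly at
#' (`bf_true`, max level).  Rectangular bands make the true Q20 exact by
#' construction.
#'
#' @param bf_true best frequency, Hz.
#' @param threshold_true response threshold, dB SPL (should be a tested level).
#' @param bw_at_threshold bandwidth at threshold, octaves.
#' @param bw_slope_per_10db bandwidth increase per 10 dB above threshold,
#'   octaves.
#' @param peak_dff peak delta-F/F of the strongest response at threshold
#'   level (> 0; set 0 for a silent neuron).
#' @param level_gain_per_10db fractional amplitude growth per 10 dB above
#'   threshold.
#' @param gcamp_tau_rise,gcamp_tau_decay indicator kernel time constants, s.
#' @param noise_sd additive per-frame fluorescence noise sd, delta-F/F units.
#' @param amp_jitter_sdlog lognormal sdlog of trial-to-trial amplitude jitter.
#' @param condition_bandwidth_gain named vector of multiplicative bandwidth
#'   factors per condition (e.g. `c(control = 1, zx1 = 1.25)`).
#' @return an object of class `rf_model`.
#' @export
receptive_field_model <- function(bf_true = 10000, threshold_true = 50,
                                  bw_at_threshold = 0.5,
                                  bw_slope_per_10db = 0.25,
                                  peak_dff = 1.0, level_gain_per_10db = 0.15,
                                  gcamp_tau_rise = 0.1, gcamp_tau_decay = 1.0,
                                  noise_sd = 0.3, amp_jitter_sdlog = 0.2,
                                  condition_bandwidth_gain = c(control = 1,
                                                               zx1 = 1.25)) {
  stop_if(bf_true <= 0, "bf_true must be positive")
  stop_if(bw_at_threshold < 0, "bandwidth must be non-negative")
  stop_if(peak_dff < 0, "peak_dff must be non-negative")
  stop_if(is.null(names(condition_bandwidth_gain)),
          "condition_bandwidth_gain must be a named vector")
  structure(list(bf_true = bf_true, threshold_true = threshold_true,
                 bw_at_threshold = bw_at_threshold,
                 bw_slope_per_10db = bw_slope_per_10db,
                 peak_dff = peak_dff, level_gain_per_10db = level_gain_per_10db,
                 gcamp_tau_rise = gcamp_tau_rise,
                 gcamp_tau_decay = gcamp_tau_decay,
                 noise_sd = noise_sd, amp_jitter_sdlog = amp_jitter_sdlog,
                 condition_bandwidth_gain = condition_bandwidth_gain),
            class = "rf_model")
}

#' Bandwidth of a receptive-field model at given levels
#'
#' @param model an `rf_model`.
#' @param levels sound levels, dB SPL.
#' @param condition condition label (applies the bandwidth gain).
#' @return bandwidth in octaves per level (0 below threshold).
#' @export
rf_bandwidth <- function(model, levels, condition = "control") {
  stop_if(!condition %in% names(model$condition_bandwidth_gain),
          "unknown condition label: ", condition)
  g <- model$condition_bandwidth_gain[[condition]]
  bw <- ifelse(levels >= model$threshold_true,
               model$bw_at_threshold +
                 model$bw_slope_per_10db * (levels - model$threshold_true) / 10,
               0)
  bw * g
}

#' Ground-truth responsive mask and amplitudes on a stimulus grid
#'
#' @param model an `rf_model`.
#' @param frequencies,levels the stimulus grid.
#' @param condition condition label.
#' @return list with `mask` (levels x frequencies logical), `amplitude`
#'   (same shape, delta-F/F peaks), and closed-form `bf`, `threshold`, `q20`
#'   ground-truth metrics on this grid (`q20` is NA when threshold + 20 dB is
#'   not a tested level, or when no stimulus is responsive).
#' @export
rf_ground_truth <- function(model, frequencies, levels, condition = "control") {
  bw <- rf_bandwidth(model, levels, condition)
  d_oct <- abs(log2(frequencies / model$bf_true))
  mask <- matrix(FALSE, length(levels), length(frequencies),
                 dimnames = list(level = levels, frequency = frequencies))
  amp <- matrix(0, length(levels), length(frequencies),
                dimnames = dimnames(mask))
  if (model$peak_dff > 0) {
    for (j in seq_along(levels)) {
      if (levels[j] < model$threshold_true || bw[j] <= 0) next
      hw <- bw[j] / 2
      inside <- d_oct <= hw + 1e-9
      mask[j, inside] <- TRUE
      lg <- 1 + model$level_gain_per_10db * (levels[j] - model$threshold_true) / 10
      amp[j, inside] <- model$peak_dff * lg * (1 - 0.5 * d_oct[inside] / hw)
    }
  }
  bf <- threshold <- q20 <- NA_real_
  if (any(mask)) {
    imax <- which(amp == max(amp), arr.ind = TRUE)
    bf <- frequencies[min(imax[, 2])]
    threshold <- min(levels[apply(mask, 1, any)])
    row20 <- which(abs(levels - (threshold + 20)) < 1e-9)
    if (length(row20) == 1 && any(mask[row20, ])) {
      fr <- frequencies[mask[row20, ]]
      q20 <- log2(max(fr) / min(fr))
    }
  }
  list(mask = mask, amplitude = amp, bf = bf, threshold = threshold, q20 = q20)
}

#' Simulate ROI fluorescence traces for a tone block session
#'
#' Generates a single neuron's somatic fluorescence across `n_repeats`
#' presentations of the stimulus block at the imaging frame rate.  Each
#' repeat's presentation order is re-drawn pseudorandomly from a seed derived
#' from `seed`.  Responsive stimuli (per the model's ground-truth mask)
#' inject a GCaMP kernel scaled by the model amplitude and a lognormal
#' trial-to-trial jitter onto a baseline of 1 fluorescence unit; white
#' Gaussian noise is added per frame.
#'
#' @param model an [receptive_field_model()].
#' @param block a `stim_block` (defines the grid and timing; per-repeat
#'   orders are re-drawn).
#' @param n_repeats number of block presentations (default 5).
#' @param condition condition label (selects the bandwidth gain).
#' @param seed integer master seed for this session.
#' @param frame_rate imaging frame rate, Hz (default 5).
#' @param pre_block_s silent padding before the first tone, s (>= 1 s so the
#'   delta-F/F baseline window exists).
#' @param post_block_s silent padding after the last tone, s.
#' @return an object of class `roi_trace`: list with `values` (frames x
#'   repeats fluorescence matrix), `frame_rate`, `repeats` (list of
#'   per-repeat presentation tables with `onset_frame`), `frequencies`,
#'   `levels`, `condition`, `n_repeats` and `ground_truth`
#'   (see [rf_ground_truth()]).
#' @export
simulate_roi_traces <- function(model, block, n_repeats = 5,
                                condition = "control", seed = 1L,
                                frame_rate = 5, pre_block_s = 2,
                                post_block_s = 3) {
  stopifnot(inherits(model, "rf_model"), inherits(block, "stim_block"))
  stop_if(n_repeats < 1, "n_repeats must be at least 1")
  stop_if(pre_block_s < 1, "pre_block_s must be at least 1 s")
  gt <- rf_ground_truth(model, block$frequencies, block$levels, condition)
  spacing <- block$duration + block$isi
  n_stim <- block$n_unique
  total_s <- pre_block_s + n_stim * spacing + post_block_s
  n_frames <- ceiling(total_s * frame_rate)
  tt <- (seq_len(n_frames) - 1) / frame_rate

  values <- matrix(1, n_frames, n_repeats)
  reps <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, 100L + r)
    ord <- with_seed(rep_seed, sample.int(n_stim))
    grid <- expand.grid(frequency_hz = block$frequencies,
                        level_db = block$levels, KEEP.OUT.ATTRS = FALSE)
    pres <- grid[ord, , drop = FALSE]
    pres$onset_s <- pre_block_s + (seq_len(n_stim) - 1) * spacing
    pres$onset_frame <- floor(pres$onset_s * frame_rate) + 1L
    rownames(pres) <- NULL
    # inject responsive stimuli
    li <- match(pres$level_db, block$levels)
    fi <- match(pres$frequency_hz, block$frequencies)
    resp <- gt$mask[cbind(li, fi)]
    if (any(resp)) {
      jit <- with_seed(derive_seed(seed, 200L + r),
                       stats::rlnorm(sum(resp), -model$amp_jitter_sdlog^2 / 2,
                                     model$amp_jitter_sdlog))
      idx <- which(resp)
      for (k in seq_along(idx)) {
        s <- idx[k]
        a <- gt$amplitude[li[s], fi[s]] * jit[k]
        t_rel <- tt - pres$onset_s[s]
        sel <- t_rel >= 0 & t_rel <= 6 * model$gcamp_tau_decay
        values[sel, r] <- values[sel, r] +
          a * gcamp_kernel(t_rel[sel], model$gcamp_tau_rise,
                           model$gcamp_tau_decay)
      }
    }
    if (model$noise_sd > 0)
      values[, r] <- values[, r] +
        with_seed(derive_seed(seed, 300L + r),
                  stats::rnorm(n_frames, 0, model$noise_sd))
    reps[[r]] <- pres
  }
  structure(list(values = values, frame_rate = frame_rate, repeats = reps,
                 frequencies = block$frequencies, levels = block$levels,
                 condition = condition, n_repeats = n_repeats,
                 ground_truth = gt),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("ROI trace: %d frames x %d repeats at %g Hz, condition '%s'\n",
              nrow(x$values), x$n_repeats, x$frame_rate, x$condition))
  cat(sprintf("  grid: %d frequencies x %d levels; true BF %s kHz, threshold %s dB, Q20 %s\n",
              length(x$frequencies), length(x$levels),
              ifelse(is.na(x$ground_truth$bf), "NA",
                     sprintf("%.1f", x$ground_truth$bf / 1000)),
              ifelse(is.na(x$ground_truth$threshold), "NA",
                     sprintf("%g", x$ground_truth$threshold)),
              ifelse(is.na(x$ground_truth$q20), "NA",
                     sprintf("%.2f oct", x$ground_truth$q20))))
  invisible(x)
}

#' Write / read ROI traces as delimited text plus JSON sidecar
#'
#' The frames x repeats fluorescence matrix is written as a tab-separated
#' table; frame rate, per-repeat alignments, grid, condition and ground
#' truth go to `<path>.json`.
#'
#' @param roi a `roi_trace`.
#' @param path path of the TSV table.
#' @return `path`, invisibly (`write_roi_trace`); a `roi_trace`
#'   (`read_roi_trace`).
#' @export
write_roi_trace <- function(roi, path) {
  stopifnot(inherits(roi, "roi_trace"))
  m <- as.data.frame(roi$values)
  names(m) <- paste0("repeat_", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- roi$ground_truth
  write_sidecar(list(frame_rate = roi$frame_rate,
                     repeats = roi$repeats,
                     frequencies = roi$frequencies, levels = roi$levels,
                     condition = roi$condition, n_repeats = roi$n_repeats,
                     ground_truth = list(mask = gt$mask, amplitude = gt$amplitude,
                                         bf = gt$bf, threshold = gt$threshold,
                                         q20 = gt$q20)),
                paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_roi_trace
#' @export
read_roi_trace <- function(path) {
  vals <- as.matrix(utils::read.delim(path))
  dimnames(vals) <- NULL
  meta <- read_sidecar(paste0(path, ".json"))
  gt <- meta$ground_truth
  gt$mask <- matrix(as.logical(gt$mask), length(meta$levels),
                    length(meta$frequencies))
  gt$amplitude <- matrix(as.numeric(unlist(gt$amplitude)), length(meta$levels),
                         length(meta$frequencies))
  structure(list(values = vals, frame_rate = meta$frame_rate,
                 repeats = lapply(meta$repeats, as.data.frame),
                 frequencies = as.numeric(meta$frequencies),
                 levels = as.numeric(meta$levels),
                 condition = meta$condition, n_repeats = meta$n_repeats,
                 ground_truth = gt),
            class = "roi_trace")
}

#' Simulate a wide-field fluorescence movie with sound-responsive regions
#'
#' Builds a pixel movie (default 150 x 200 at 20 Hz) containing Gaussian
#' spatial blobs — emulating the low-frequency tonotopic fields of A1 and the
#' AAF responding to a low-level 6 kHz mapping tone — whose temporal profile
#' follows a GCaMP kernel after each tone onset, on a uniform baseline, plus
#' white pixel noise.
#'
#' @param regions list of region specs, each a list with `center` (pixel
#'   c(row, col)), `radius` (Gaussian sigma, px) and `amplitude` (peak
#'   delta-F/F).
#' @param onsets tone onset times, s.
#' @param tone_duration tone duration, s.
#' @param total_s movie duration, s.
#' @param dims frame dimensions, c(rows, cols); default `c(150, 200)`.
#' @param frame_rate frames per second (default 20).
#' @param baseline baseline fluorescence, a.u.
#' @param noise_sd pixel noise sd in delta-F/F units.
#' @param seed integer seed.
#' @return an object of class `widefield_movie`: list with `frames` (array
#'   rows x cols x n_frames), `frame_rate`, `onsets`, `tone_duration`,
#'   `regions` (ground truth).
#' @export
simulate_widefield_movie <- function(regions, onsets = 1.5, tone_duration = 0.5,
                                     total_s = 5, dims = c(150, 200),
                                     frame_rate = 20, baseline = 100,
                                     noise_sd = 0.02, seed = 1L) {
  stop_if(length(regions) < 1, "at least one region spec required")
  for (rg in regions) {
    stop_if(rg$center[1] < 1 || rg$center[1] > dims[1] ||
              rg$center[2] < 1 || rg$center[2] > dims[2],
            "region centre outside the frame")
  }
  n_frames <- round(total_s * frame_rate)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  spatial <- matrix(0, dims[1], dims[2])
  for (rg in regions) {
    spatial <- spatial + rg$amplitude *
      exp(-((rr - rg$center[1])^2 + (cc - rg$center[2])^2) / (2 * rg$radius^2))
  }
  temporal <- numeric(n_frames)
  for (on in onsets)
    temporal <- temporal + gcamp_kernel(tt - on, 0.1, 1.0)
  frames <- array(baseline, c(dims, n_frames))
  for (k in seq_len(n_frames))
    frames[, , k] <- baseline * (1 + spatial * temporal[k])
  if (noise_sd > 0)
    frames <- frames + with_seed(seed,
      array(stats::rnorm(length(frames), 0, baseline * noise_sd), dim(frames)))
  frames[frames < 0] <- 0
  structure(list(frames = frames, frame_rate = frame_rate, onsets = onsets,
                 tone_duration = tone_duration, regions = regions),
            class = "widefield_movie")
}

#' @export
print.widefield_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Wide-field movie: %d x %d px, %d frames at %g Hz, %d ground-truth region(s)\n",
              d[2], d[1], d[3], x$frame_rate, length(x$regions)))
  invisible(x)
}
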
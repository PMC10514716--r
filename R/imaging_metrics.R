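#' Delta-F/F around a stimulus onset
#'
#' Normalises the stimulus-evoked change in fluorescence to the baseline F,
#' where F is the mean fluorescence over the 1 s preceding the onset frame.
#'
#' @param values fluorescence vector (one ROI or pixel), a.u.
#' @param onset_frame index of the frame containing the stimulus onset.
#' @param frame_rate frames per second.
#' @param pre_s baseline window length, s (default 1).
#' @param post_frames number of frames returned from the onset frame onward;
#'   default to the end of the trace.
#' @param include_pre if TRUE the returned series also covers the baseline
#'   window.
#' @return list with `dff` (numeric series), `f0` (baseline) and `flagged`
#'   (TRUE when `f0 <= 0`, in which case `dff` is NA).
#' @export
compute_dff <- function(values, onset_frame, frame_rate, pre_s = 1,
                        post_frames = NULL, include_pre = FALSE) {
  n_pre <- round(pre_s * frame_rate)
  stop_if(onset_frame - n_pre < 1,
          "insufficient pre-onset frames for the baseline window")
  stop_if(onset_frame > length(values), "onset frame beyond trace end")
  if (is.null(post_frames)) post_frames <- length(values) - onset_frame + 1L
  stop_if(onset_frame + post_frames - 1L > length(values),
          "requested window extends past trace end")
  f0 <- mean(values[(onset_frame - n_pre):(onset_frame - 1L)])
  i0 <- if (include_pre) onset_frame - n_pre else onset_frame
  seg <- values[i0:(onset_frame + post_frames - 1L)]
  if (f0 <= 0)
    return(list(dff = rep(NA_real_, length(seg)), f0 = f0, flagged = TRUE))
  list(dff = (seg - f0) / f0, f0 = f0, flagged = FALSE)
}

#' Two-dimensional Butterworth low-pass filter
#'
#' Frequency-domain filter with magnitude response
#' `H(r) = 1 / sqrt(1 + (r / cutoff)^(2 order))`, where r is the radial
#' spatial frequency in cycles/pixel.  Applied via the 2-D FFT; the output is
#' real.
#'
#' @param img numeric matrix.
#' @param cutoff normalized cutoff frequency, cycles/pixel (0 < cutoff <=
#'   0.5 is meaningful; default 0.1).
#' @param order filter order (default 2).
#' @return filtered matrix, same dimensions.
#' @export
butterworth2d <- function(img, cutoff = 0.1, order = 2) {
  stop_if(cutoff <= 0, "cutoff must be positive")
  d <- dim(img)
  fu <- (seq_len(d[1]) - 1) / d[1]
  fu <- pmin(fu, 1 - fu)
  fv <- (seq_len(d[2]) - 1) / d[2]
  fv <- pmin(fv, 1 - fv)
  r <- sqrt(outer(fu^2, fv^2, `+`))
  H <- 1 / sqrt(1 + (r / cutoff)^(2 * order))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / length(img)
}

#' Wide-field response map
#'
#' Converts a wide-field movie to a per-pixel delta-F/F movie (baseline =
#' mean of the 1 s preceding each tone onset), low-pass filters each frame
#' with a 2-D Butterworth filter, and averages the 10 consecutive frames
#' (0.5 s at 20 Hz) beginning at the end of the sound stimulus.  With several
#' onsets the per-onset maps are averaged.
#'
#' @param movie a `widefield_movie`.
#' @param onsets tone onset times, s; default the movie's own.
#' @param tone_duration tone duration, s; default the movie's own.
#' @param n_avg_frames frames averaged from sound offset (default 10).
#' @param cutoff,order Butterworth parameters (see [butterworth2d()]).
#' @return an object of class `response_map`: list with `dff_image` (matrix),
#'   `filtered = TRUE`, `n_avg_frames`, `frame_rate`.
#' @export
widefield_map <- function(movie, onsets = movie$onsets,
                          tone_duration = movie$tone_duration,
                          n_avg_frames = 10, cutoff = 0.1, order = 2) {
  stopifnot(inherits(movie, "widefield_movie"))
  fr <- movie$frame_rate
  d <- dim(movie$frames)
  acc <- matrix(0, d[1], d[2])
  for (on in onsets) {
    onset_frame <- floor(on * fr) + 1L
    n_pre <- round(fr)
    stop_if(onset_frame - n_pre < 1, "insufficient pre-onset frames")
    offset_frame <- floor((on + tone_duration) * fr) + 1L
    stop_if(offset_frame + n_avg_frames - 1L > d[3],
            "fewer than ", n_avg_frames, " frames after sound offset")
    f0 <- apply(movie$frames[, , (onset_frame - n_pre):(onset_frame - 1L),
                             drop = FALSE], c(1, 2), mean)
    m <- matrix(0, d[1], d[2])
    for (k in offset_frame:(offset_frame + n_avg_frames - 1L)) {
      dff <- (movie$frames[, , k] - f0) / f0
      m <- m + butterworth2d(dff, cutoff, order)
    }
    acc <- acc + m / n_avg_frames
  }
  structure(list(dff_image = acc / length(onsets), filtered = TRUE,
                 n_avg_frames = n_avg_frames, frame_rate = fr),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  d <- dim(x$dff_image)
  cat(sprintf("Response map: %d x %d px (mean of %d filtered dF/F frames); range %.3g..%.3g\n",
              d[2], d[1], x$n_avg_frames, min(x$dff_image), max(x$dff_image)))
  invisible(x)
}

#' Detect sound-responsive regions in a response map
#'
#' Pixels exceeding `mean + z_thresh * sd` of the map form 8-connected
#' components; components of at least `min_area_px` pixels are returned
#' sorted by decreasing area.
#'
#' @param map a `response_map`.
#' @param z_thresh threshold in map standard deviations above the mean.
#' @param min_area_px minimum component area, pixels.
#' @return data.frame with one row per region: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `peak_dff`.
#' @export
detect_regions <- function(map, z_thresh = 3, min_area_px = 5) {
  stopifnot(inherits(map, "response_map"))
  img <- map$dff_image
  thr <- mean(img) + z_thresh * stats::sd(img)
  mask <- img > thr
  if (!any(mask))
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      peak_dff = numeric()))
  lab <- EBImage::bwlabel(mask)
  labs <- sort(unique(as.vector(lab)))
  labs <- labs[labs > 0]
  out <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    data.frame(label = l, area_px = nrow(idx),
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               peak_dff = max(img[lab == l]))
  }))
  out <- out[out$area_px >= min_area_px, , drop = FALSE]
  out <- out[order(-out$area_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z-score a trace
#'
#' Subtracts the mean of the entire trace from every time point and divides
#' by the standard deviation of the entire trace.  The population convention
#' (divide by N) is the default; the sample convention (N - 1) is available.
#'
#' @param x numeric trace (length >= 2).
#' @param convention `"population"` (default) or `"sample"`.
#' @return list with `z` (the standardized trace; NA when flagged) and
#'   `flagged` (TRUE when the trace has zero standard deviation).
#' @export
zscore_trace <- function(x, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  stop_if(length(x) < 2, "trace too short to standardize")
  mu <- mean(x)
  s <- stats::sd(x)
  if (convention == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0)
    return(list(z = rep(NA_real_, length(x)), flagged = TRUE))
  list(z = (x - mu) / s, flagged = FALSE)
}

#' Detect a sound-evoked response in a Z-scored trace
#'
#' A stimulus counts as a response if the Z-scored fluorescence exceeds
#' `z_thresh` (default 0.6) for at least `min_consec` (default 2) consecutive
#' frames within the 1 s following the sound onset.  The window is half-open:
#' `[onset_frame, onset_frame + round(window_s * frame_rate))`, and both
#' criterion frames must lie inside it.  The response size is the peak Z
#' value in the window.
#'
#' @param z Z-scored trace.
#' @param onset_frame index of the frame containing the sound onset.
#' @param frame_rate frames per second.
#' @param z_thresh detection threshold in Z units.
#' @param min_consec required consecutive supra-threshold frames.
#' @param window_s quantification window, s (default 1).
#' @return list with `responsive` (logical) and `peak_z` (max in-window Z).
#' @export
detect_response <- function(z, onset_frame, frame_rate, z_thresh = 0.6,
                            min_consec = 2, window_s = 1) {
  n_win <- round(window_s * frame_rate)
  stop_if(onset_frame < 1 || onset_frame + n_win - 1L > length(z),
          "quantification window truncated by trace end")
  w <- z[onset_frame:(onset_frame + n_win - 1L)]
  above <- w > z_thresh
  r <- rle(above)
  responsive <- any(r$values & r$lengths >= min_consec)
  list(responsive = responsive, peak_z = max(w))
}

#' Build a frequency-intensity tuning surface from ROI traces
#'
#' For every (frequency, level) combination the repeat-aligned delta-F/F
#' responses are averaged across the 5-7 block presentations; the averaged
#' per-stimulus responses are concatenated (in grid order) into the neuron's
#' average-response trace, which is converted to Z scores using the mean and
#' standard deviation of that entire trace; responses are then detected per
#' stimulus with the consecutive-frame criterion in the 1-s post-onset
#' window.
#'
#' @param roi a `roi_trace` (see [simulate_roi_traces()] /
#'   [read_roi_trace()]).
#' @param z_thresh,min_consec detection parameters (see [detect_response()]).
#' @param pre_s baseline window, s.
#' @param post_s response segment length after onset, s (>= 1).
#' @param sd_convention Z-score convention (see [zscore_trace()]).
#' @return an object of class `tuning_surface`: list with `peak_z` and
#'   `responsive` (levels x frequencies matrices), `frequencies`, `levels`,
#'   `avg_dff` (levels x frequencies x segment-frames array),
#'   `repeat_windows` (per-repeat evoked/baseline peak delta-F/F at every
#'   stimulus, used by [dprime_neuron()]), `repeats_used`, `flagged`
#'   (TRUE when the whole trace had zero variance).
#' @export
build_tuning_surface <- function(roi, z_thresh = 0.6, min_consec = 2,
                                 pre_s = 1, post_s = 2,
                                 sd_convention = "population") {
  stopifnot(inherits(roi, "roi_trace"))
  fr <- roi$frame_rate
  n_pre <- round(pre_s * fr)
  n_post <- round(post_s * fr)
  n_win <- round(fr)                      # 1-s detection window
  stop_if(n_post < n_win, "post_s must cover the 1-s quantification window")
  nf <- length(roi$frequencies)
  nl <- length(roi$levels)
  n_stim <- nf * nl
  seg_len <- n_pre + n_post

  # grid-ordered accumulation: rows keyed as level + (frequency - 1) * nl
  acc_mat <- matrix(0, n_stim, seg_len)
  cnt <- integer(n_stim)
  ev_peak <- array(NA_real_, c(nl, nf, roi$n_repeats))
  bl_peak <- array(NA_real_, c(nl, nf, roi$n_repeats))
  win_cols <- (n_pre + 1L):(n_pre + n_win)

  for (r in seq_len(roi$n_repeats)) {
    pres <- roi$repeats[[r]]
    stop_if(nrow(pres) != n_stim, "repeat ", r, " is missing stimuli")
    v <- roi$values[, r]
    of <- pres$onset_frame
    stop_if(any(of - n_pre < 1) || any(of + n_post - 1L > length(v)),
            "stimulus window extends past the trace in repeat ", r)
    seg <- matrix(v[outer(of, (-n_pre):(n_post - 1L), `+`)], n_stim, seg_len)
    base <- rowMeans(seg[, 1:n_pre, drop = FALSE])
    usable <- base > 0
    dff <- (seg - base) / base
    li <- match(pres$level_db, roi$levels)
    fi <- match(pres$frequency_hz, roi$frequencies)
    key <- li + (fi - 1L) * nl
    ord <- order(key)
    acc_mat[key[ord][usable[ord]], ] <- acc_mat[key[ord][usable[ord]], ] +
      dff[ord, , drop = FALSE][usable[ord], , drop = FALSE]
    cnt[key[usable]] <- cnt[key[usable]] + 1L
    ev_peak[cbind(li, fi, r)] <- ifelse(usable,
      do.call(pmax, as.data.frame(dff[, win_cols, drop = FALSE])), NA_real_)
    bl_peak[cbind(li, fi, r)] <- ifelse(usable,
      do.call(pmax, as.data.frame(dff[, 1:n_pre, drop = FALSE])), NA_real_)
  }
  stop_if(any(cnt == 0), "at least one stimulus has no usable repeat")
  avg_mat <- acc_mat / cnt
  avg <- array(NA_real_, c(nl, nf, seg_len))
  for (k in seq_len(seg_len)) avg[, , k] <- matrix(avg_mat[, k], nl, nf)

  # concatenate averaged responses (grid order) into the entire trace
  entire <- as.vector(aperm(avg, c(3, 2, 1)))   # seg fastest, then freq, level
  zs <- zscore_trace(entire, convention = sd_convention)
  peak_z <- matrix(NA_real_, nl, nf,
                   dimnames = list(level = roi$levels,
                                   frequency = roi$frequencies))
  responsive <- matrix(FALSE, nl, nf, dimnames = dimnames(peak_z))
  if (!zs$flagged) {
    z_arr <- aperm(array(zs$z, c(seg_len, nf, nl)), c(3, 2, 1))
    for (li in seq_len(nl)) for (fi in seq_len(nf)) {
      det <- detect_response(z_arr[li, fi, ], n_pre + 1L, fr,
                             z_thresh = z_thresh, min_consec = min_consec)
      peak_z[li, fi] <- det$peak_z
      responsive[li, fi] <- det$responsive
    }
  }
  structure(list(peak_z = peak_z, responsive = responsive,
                 frequencies = roi$frequencies, levels = roi$levels,
                 avg_dff = avg,
                 repeat_windows = list(evoked = ev_peak, baseline = bl_peak),
                 repeats_used = roi$n_repeats, flagged = zs$flagged),
            class = "tuning_surface")
}

#' @export
print.tuning_surface <- function(x, ...) {
  cat(sprintf("Tuning surface: %d levels x %d frequencies, %d repeats; %d responsive combination(s)\n",
              length(x$levels), length(x$frequencies), x$repeats_used,
              sum(x$responsive)))
  invisible(x)
}

#' Best frequency
#'
#' The sound frequency of the largest detected response, independent of
#' sound level.  Exact ties are broken toward the lower frequency.
#'
#' @param surface a `tuning_surface`.
#' @return list with `bf` (Hz, NA when flagged) and `flagged`.
#' @export
best_frequency <- function(surface) {
  stopifnot(inherits(surface, "tuning_surface"))
  if (!any(surface$responsive))
    return(list(bf = NA_real_, flagged = TRUE))
  pz <- surface$peak_z
  pz[!surface$responsive] <- -Inf
  best <- max(pz)
  hit <- which(pz == best, arr.ind = TRUE)
  list(bf = surface$frequencies[min(hit[, 2])], flagged = FALSE)
}

#' Response threshold
#'
#' The lowest sound level with a detected response at any frequency.
#'
#' @param surface a `tuning_surface`.
#' @return list with `threshold` (dB SPL, NA when flagged) and `flagged`.
#' @export
response_threshold <- function(surface) {
  stopifnot(inherits(surface, "tuning_surface"))
  rows <- apply(surface$responsive, 1, any)
  if (!any(rows)) return(list(threshold = NA_real_, flagged = TRUE))
  list(threshold = min(surface$levels[rows]), flagged = FALSE)
}

#' Q20 receptive-field bandwidth
#'
#' log2 of the ratio of the highest to the lowest sound frequency eliciting
#' a response at the level row 20 dB above threshold.  Returns 0 when exactly
#' one frequency responds at that row; undefined (flagged) when threshold +
#' 20 dB is not a tested level — such neurons are excluded from bandwidth
#' analyses.
#'
#' @param surface a `tuning_surface`.
#' @return list with `q20` (octaves, NA when flagged) and `flagged`.
#' @export
q20_bandwidth <- function(surface) {
  stopifnot(inherits(surface, "tuning_surface"))
  thr <- response_threshold(surface)
  if (thr$flagged) return(list(q20 = NA_real_, flagged = TRUE))
  row20 <- which(abs(surface$levels - (thr$threshold + 20)) < 1e-9)
  if (length(row20) != 1) return(list(q20 = NA_real_, flagged = TRUE))
  resp <- surface$responsive[row20, ]
  if (!any(resp)) return(list(q20 = NA_real_, flagged = TRUE))
  f <- surface$frequencies[resp]
  list(q20 = log2(max(f) / min(f)), flagged = FALSE)
}

#' d-prime responsiveness index for one neuron
#'
#' Discriminability of the evoked response at the neuron's best frequency
#' from baseline:
#' `d' = (mean evoked - mean baseline) / sqrt((var_evoked + var_baseline)/2)`,
#' where per repeat the evoked value is the peak delta-F/F in the 1-s
#' post-onset window of the BF stimulus (at the level of the global maximum)
#' and the baseline value is the peak over the matched-duration window
#' immediately preceding that onset.
#'
#' @param surface a `tuning_surface` (carries the per-repeat windows).
#' @return list with `dprime` (NA when flagged) and `flagged` (no responsive
#'   stimulus, < 2 repeats, or zero pooled variance).
#' @export
dprime_neuron <- function(surface) {
  stopifnot(inherits(surface, "tuning_surface"))
  if (!any(surface$responsive) || surface$repeats_used < 2)
    return(list(dprime = NA_real_, flagged = TRUE))
  pz <- surface$peak_z
  pz[!surface$responsive] <- -Inf
  hit <- which(pz == max(pz), arr.ind = TRUE)
  li <- hit[1, 1]; fi <- surface$frequencies == surface$frequencies[min(hit[, 2])]
  fi <- which(fi)[1]
  ev <- surface$repeat_windows$evoked[li, fi, ]
  bl <- surface$repeat_windows$baseline[li, fi, ]
  ok <- is.finite(ev) & is.finite(bl)
  ev <- ev[ok]; bl <- bl[ok]
  if (length(ev) < 2) return(list(dprime = NA_real_, flagged = TRUE))
  pooled <- (stats::var(ev) + stats::var(bl)) / 2
  if (pooled == 0) return(list(dprime = NA_real_, flagged = TRUE))
  list(dprime = (mean(ev) - mean(bl)) / sqrt(pooled), flagged = FALSE)
}

#' Select the most responsive fraction of neurons
#'
#' Ranks sound-responsive neurons by d-prime (descending) and keeps
#' `ceiling(fraction * n)`, at least 1.  Ties at the cutoff are broken by
#' rank stability (earlier input wins).
#'
#' @param dprimes numeric d-prime values (only sound-responsive neurons
#'   should be supplied); NAs are never selected.
#' @param fraction fraction kept (default 0.20).
#' @return integer indices (into `dprimes`) of the selected neurons.
#' @export
select_top_fraction <- function(dprimes, fraction = 0.20) {
  stop_if(fraction <= 0 || fraction > 1, "fraction must lie in (0, 1]")
  ok <- which(is.finite(dprimes))
  if (length(ok) == 0) return(integer())
  k <- max(1L, ceiling(fraction * length(ok)))
  ord <- ok[order(-dprimes[ok], ok)]      # stable: ties keep input order
  sort(ord[seq_len(min(k, length(ord)))])
}

#' Full tuning quantification for one neuron
#'
#' @param roi a `roi_trace`.
#' @param ... passed to [build_tuning_surface()].
#' @return an object of class `tuning_metrics`: list with `bf`, `threshold`,
#'   `q20`, `dprime`, `is_sound_responsive` and the underlying `surface`.
#' @export
tuning_metrics <- function(roi, ...) {
  surf <- build_tuning_surface(roi, ...)
  bf <- best_frequency(surf)
  thr <- response_threshold(surf)
  q <- q20_bandwidth(surf)
  dp <- dprime_neuron(surf)
  structure(list(bf = bf$bf, threshold = thr$threshold, q20 = q$q20,
                 dprime = dp$dprime,
                 is_sound_responsive = any(surf$responsive),
                 surface = surf),
            class = "tuning_metrics")
}

#' @export
print.tuning_metrics <- function(x, ...) {
  cat(sprintf("Tuning metrics: %s | BF %s kHz | threshold %s dB SPL | Q20 %s | d' %s\n",
              if (x$is_sound_responsive) "sound-responsive" else "not responsive",
              ifelse(is.na(x$bf), "NA", sprintf("%.1f", x$bf / 1000)),
              ifelse(is.na(x$threshold), "NA", sprintf("%g", x$threshold)),
              ifelse(is.na(x$q20), "NA", sprintf("%.2f oct", x$q20)),
              ifelse(is.na(x$dprime), "NA", sprintf("%.2f", x$dprime))))
  invisible(x)
}
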
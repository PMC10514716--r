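#' Experiment configuration
#'
#' Builds a validated configuration for a seeded end-to-end experiment.
#' Every stochastic stage receives a seed derived deterministically from the
#' master seed, so identical configurations reproduce identical bundles and
#' individual stages can be rerun in isolation.
#'
#' @param track `"ephys"`, `"imaging"` or `"widefield"`.
#' @param seed master integer seed.
#' @param ... track-specific overrides.  Unknown keys are rejected by name.
#'   Ephys track: `n_cells` (6), `n_trials` (3), `condition_gain` (0.75),
#'   `base_amplitude` (100 pA), `noise_sd` (base/20), `train_rates_hz`
#'   (c(5, 10)), `n_pulses` (5), `release_fraction` (0.4), `tau_recovery`
#'   (200 ms), `rs_fail_cells` (integer(), cells given a drifting
#'   series-resistance log), `scheme` ("pointwise_vs_control"), `alpha`
#'   (0.05).  Imaging track: `n_neurons` (40), `n_repeats` (5),
#'   `bandwidth_gain` (1.25), `noise_sd` (0.3), `thresholds` (c(40, 50, 60)),
#'   `alpha` (0.05), `block_seed` (derived).  Widefield track: `noise_sd`
#'   (0.02), `n_regions` (2).
#' @return an object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(track = c("ephys", "imaging", "widefield"),
                              seed = 1L, ...) {
  track <- match.arg(track)
  defaults <- switch(track,
    ephys = list(n_cells = 6L, n_trials = 3L, condition_gain = 0.75,
                 base_amplitude = 100, noise_sd = NULL,
                 train_rates_hz = c(5, 10), n_pulses = 5L,
                 release_fraction = 0.4, tau_recovery = 200,
                 rs_fail_cells = integer(), scheme = "pointwise_vs_control",
                 alpha = 0.05),
    imaging = list(n_neurons = 40L, n_repeats = 5L, bandwidth_gain = 1.25,
                   noise_sd = 0.3, thresholds = c(40, 50, 60), alpha = 0.05,
                   block_seed = NULL),
    widefield = list(noise_sd = 0.02, n_regions = 2L))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  stop_if(length(bad) > 0, "invalid config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  cfg$track <- track
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config: track '%s', seed %d\n", x$track, x$seed))
  keys <- setdiff(names(x), c("track", "seed"))
  for (k in keys)
    cat(sprintf("  %s = %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

#' Run a configured experiment
#'
#' Dispatches to the track-specific driver.
#'
#' @param config an [experiment_config()].
#' @return a results bundle (see the track drivers).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$track,
         ephys = run_ephys_experiment(config),
         imaging = run_imaging_experiment(config),
         widefield = run_widefield_experiment(config))
}

manifest_of <- function(config) {
  keys <- sort(names(config))
  desc <- paste(vapply(keys, function(k)
    paste0(k, "=", paste(format(config[[k]]), collapse = ",")), character(1)),
    collapse = ";")
  list(seed = config$seed, track = config$track,
       config = desc,
       package_version = as.character(utils::packageVersion("audsynth")))
}

#' Run a seeded EPSC-train experiment
#'
#' Composes the generators and metrics end to end: simulated cells each
#' recorded in a control and a chelator condition (single pulse plus trains),
#' trial averaging, QC exclusion, per-pulse amplitude metrics, the requested
#' normalisation scheme, and the group statistics (paired comparison of
#' first-pulse amplitudes; two-way repeated-measures ANOVA of normalised
#' train amplitudes per rate; Holm-Bonferroni over the family).
#'
#' @param config an [experiment_config()] with `track = "ephys"`.
#' @return an object of class `ephys_experiment`: list with `metrics`
#'   (data.frame cell x condition x protocol), `normalized` (data.frame of
#'   per-pulse normalised amplitudes), `excluded` (data.frame of QC
#'   exclusions with reasons), `stats` (list of `comparison_result`s plus
#'   Holm decisions), `manifest` and `config`.
#' @export
run_ephys_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$track == "ephys")
  seed <- config$seed
  protocols <- c("single", if (length(config$train_rates_hz))
    paste0("train", config$train_rates_hz))
  conditions <- c("control", "chelator")

  metrics <- list(); normalized <- list(); excluded <- list()
  a1 <- array(NA_real_, c(config$n_cells, 2),
              dimnames = list(NULL, conditions))
  train_norm <- list()

  for (cell in seq_len(config$n_cells)) {
    cell_seed <- derive_seed(seed, cell)
    base_amp <- config$base_amplitude *
      with_seed(derive_seed(cell_seed, 1L), stats::rlnorm(1, 0, 0.2))
    noise_sd <- if (is.null(config$noise_sd)) base_amp / 20 else config$noise_sd
    model <- synapse_model(base_amplitude = base_amp,
                           release_fraction = config$release_fraction,
                           tau_recovery = config$tau_recovery,
                           condition_gain = c(control = 1,
                                              chelator = config$condition_gain),
                           noise_sd = noise_sd)
    rs_log <- if (cell %in% config$rs_fail_cells)
      simulate_rs_log(25, 0.20, 5) else simulate_rs_log(15, 0.05, 5)
    qc <- qc_series_resistance(rs_log)
    if (!qc$pass) {
      excluded[[length(excluded) + 1]] <-
        data.frame(cell = cell, reason = qc$reason)
      next
    }
    amps_by <- list()
    for (p in seq_along(protocols)) {
      proto <- protocols[p]
      onsets <- if (proto == "single") 0.05 else
        0.05 + seq(0, by = 1 / config$train_rates_hz[p - 1],
                   length.out = config$n_pulses)
      for (ci in seq_along(conditions)) {
        cond <- conditions[ci]
        sweeps <- lapply(seq_len(config$n_trials), function(tr)
          simulate_epsc_train(model, onsets, cond,
                              seed = derive_seed(cell_seed,
                                                 1000L * p + 10L * ci + tr),
                              rs_log = rs_log))
        avg <- average_trials(sweeps)
        m <- epsc_train_metrics(avg)
        amps_by[[paste(proto, cond)]] <- m$amplitudes
        metrics[[length(metrics) + 1]] <- data.frame(
          cell = cell, condition = cond, protocol = proto,
          a1_pA = m$amplitudes[1], ppr = m$ppr, steady_state = m$steady_state,
          decay_tau_ms = m$decay_tau, qc_pass = m$qc$pass)
        if (proto == "single" && cond == "control") a1[cell, 1] <- m$amplitudes[1]
        if (proto == "single" && cond == "chelator") a1[cell, 2] <- m$amplitudes[1]
      }
      nt <- normalize_train(amps_by[[paste(proto, "chelator")]],
                            amps_by[[paste(proto, "control")]],
                            scheme = config$scheme)
      normalized[[length(normalized) + 1]] <- data.frame(
        cell = cell, protocol = proto, scheme = config$scheme,
        pulse = seq_along(nt$values), value = nt$values)
      if (proto != "single") {
        wt <- normalize_train(amps_by[[paste(proto, "chelator")]],
                              amps_by[[paste(proto, "control")]],
                              scheme = "train_vs_first_control")
        wc <- normalize_train(amps_by[[paste(proto, "control")]],
                              amps_by[[paste(proto, "control")]],
                              scheme = "train_vs_first_control")
        train_norm[[proto]] <- c(train_norm[[proto]],
                                 list(rbind(chelator = wt$values,
                                            control = wc$values)))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  normalized <- do.call(rbind, normalized)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(cell = integer(), reason = character())

  surv <- stats::complete.cases(a1)
  stats_out <- list()
  if (sum(surv) >= 3)
    stats_out$first_pulse <- paired_compare(a1[surv, "control"],
                                            a1[surv, "chelator"],
                                            alpha = config$alpha)
  for (proto in names(train_norm)) {
    mats <- train_norm[[proto]]
    arr <- array(NA_real_, c(length(mats), 2, ncol(mats[[1]])))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    if (length(mats) >= 2)
      stats_out[[paste0(proto, "_rm_anova")]] <- rm_anova_two_way(arr,
                                                                  alpha = config$alpha)
  }
  ps <- vapply(stats_out, `[[`, numeric(1), "p_value")
  stats_out$holm <- if (length(ps)) holm_bonferroni(ps, config$alpha) else NULL

  structure(list(metrics = metrics, normalized = normalized,
                 excluded = excluded, stats = stats_out,
                 first_pulse_amplitudes = a1,
                 manifest = manifest_of(config), config = config),
            class = "ephys_experiment")
}

#' @export
print.ephys_experiment <- function(x, ...) {
  cat(sprintf("Ephys experiment bundle: %d cells analysed, %d excluded (seed %d)\n",
              length(unique(x$metrics$cell)), nrow(x$excluded),
              x$config$seed))
  if (!is.null(x$stats$first_pulse)) {
    fp <- x$stats$first_pulse
    cat(sprintf("  first-pulse %s: p = %.4g (median chelator/control = %.3f)\n",
                fp$test_name, fp$p_value,
                stats::median(x$first_pulse_amplitudes[, 2] /
                                x$first_pulse_amplitudes[, 1], na.rm = TRUE)))
  }
  invisible(x)
}

#' Run a seeded awake-imaging tuning experiment
#'
#' Simulates a cohort of neurons, each imaged in a paired control and
#' chelator-infusion condition in which the receptive-field bandwidth is
#' multiplied by `bandwidth_gain`; extracts per-neuron tuning metrics (BF,
#' threshold, Q20, d-prime), forms the paired Q20 differences over neurons
#' with a defined Q20 in both conditions, and tests them with the Wilcoxon
#' signed-rank test (the presentation used for cumulative Q20
#' distributions).
#'
#' @param config an [experiment_config()] with `track = "imaging"`.
#' @return an object of class `imaging_experiment`: list with `neurons`
#'   (per-neuron metrics data.frame), `delta_q20`, `stats` (signed-rank
#'   `comparison_result` and the decision-tree [paired_compare()] result),
#'   `top_fraction` (indices of the top-20%-by-d-prime subset among
#'   sound-responsive neurons in control), `cumdist` (sorted Q20 values per
#'   condition), `manifest`, `config`.
#' @export
run_imaging_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$track == "imaging")
  seed <- config$seed
  block_seed <- if (is.null(config$block_seed)) derive_seed(seed, 7L) else
    config$block_seed
  block <- build_tone_block(seed = block_seed)
  freqs <- block$frequencies
  # candidate BFs far enough from the grid edges that the widest band fits
  interior <- which(log2(freqs / min(freqs)) >= 1 &
                      log2(max(freqs) / freqs) >= 1)
  rows <- vector("list", config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    ns <- derive_seed(seed, 10L + i)
    draw <- with_seed(ns, list(bf = freqs[sample(interior, 1)],
                               thr = sample(config$thresholds, 1)))
    model <- receptive_field_model(
      bf_true = draw$bf, threshold_true = draw$thr,
      noise_sd = config$noise_sd,
      condition_bandwidth_gain = c(control = 1, zx1 = config$bandwidth_gain))
    per_cond <- lapply(c(control = "control", zx1 = "zx1"), function(cond) {
      roi <- simulate_roi_traces(model, block, n_repeats = config$n_repeats,
                                 condition = cond,
                                 seed = derive_seed(ns, match(cond,
                                                              c("control", "zx1"))))
      tuning_metrics(roi)
    })
    rows[[i]] <- data.frame(
      neuron = i, bf_true = draw$bf, threshold_true = draw$thr,
      condition = c("control", "zx1"),
      responsive = vapply(per_cond, `[[`, logical(1), "is_sound_responsive"),
      bf = vapply(per_cond, `[[`, numeric(1), "bf"),
      threshold = vapply(per_cond, `[[`, numeric(1), "threshold"),
      q20 = vapply(per_cond, `[[`, numeric(1), "q20"),
      dprime = vapply(per_cond, `[[`, numeric(1), "dprime"))
  }
  neurons <- do.call(rbind, rows)
  ctl <- neurons[neurons$condition == "control", ]
  trt <- neurons[neurons$condition == "zx1", ]
  ok <- is.finite(ctl$q20) & is.finite(trt$q20)
  dq <- trt$q20[ok] - ctl$q20[ok]

  stats_out <- list()
  if (sum(ok) >= 3) {
    exact <- sum(ok) <= 25
    sr <- suppressWarnings(stats::wilcox.test(trt$q20[ok], ctl$q20[ok],
                                              paired = TRUE, exact = exact,
                                              correct = TRUE))
    stats_out$signed_rank <- structure(
      list(test_name = "Wilcoxon signed-rank test",
           statistic = unname(sr$statistic), p_value = sr$p.value,
           n = sum(ok), normality_p = NA_real_,
           reject = sr$p.value < config$alpha, degenerate = FALSE),
      class = "comparison_result")
    stats_out$decision_tree <- paired_compare(trt$q20[ok], ctl$q20[ok],
                                              alpha = config$alpha)
  }
  resp_idx <- which(ctl$responsive & is.finite(ctl$dprime))
  top <- resp_idx[select_top_fraction(ctl$dprime[resp_idx])]

  structure(list(neurons = neurons, delta_q20 = dq, stats = stats_out,
                 top_fraction = top,
                 cumdist = list(control = sort(ctl$q20[ok]),
                                zx1 = sort(trt$q20[ok])),
                 manifest = manifest_of(config), config = config),
            class = "imaging_experiment")
}

#' @export
print.imaging_experiment <- function(x, ...) {
  cat(sprintf("Imaging experiment bundle: %d neurons, %d paired Q20s (seed %d)\n",
              length(unique(x$neurons$neuron)), length(x$delta_q20),
              x$config$seed))
  if (!is.null(x$stats$signed_rank))
    cat(sprintf("  median dQ20 = %+.3f octaves, signed-rank p = %.4g%s\n",
                stats::median(x$delta_q20), x$stats$signed_rank$p_value,
                if (x$stats$signed_rank$reject) " (*)" else ""))
  invisible(x)
}

#' Run a seeded wide-field mapping experiment
#'
#' Simulates a movie with two sound-responsive fields (emulating A1 and the
#' AAF responding to a low-level 6 kHz mapping tone), computes the filtered,
#' time-averaged delta-F/F response map and detects the regions.
#'
#' @param config an [experiment_config()] with `track = "widefield"`.
#' @return an object of class `widefield_experiment`: list with `map`
#'   (`response_map`), `regions` (detected), `truth` (simulated region
#'   specs), `manifest`, `config`.
#' @export
run_widefield_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$track == "widefield")
  truth <- list(list(center = c(60, 70), radius = 8, amplitude = 0.08),
                list(center = c(90, 140), radius = 8, amplitude = 0.06))
  truth <- truth[seq_len(min(config$n_regions, length(truth)))]
  movie <- simulate_widefield_movie(truth, noise_sd = config$noise_sd,
                                    seed = derive_seed(config$seed, 1L))
  map <- widefield_map(movie)
  regions <- detect_regions(map)
  structure(list(map = map, regions = regions, truth = truth,
                 manifest = manifest_of(config), config = config),
            class = "widefield_experiment")
}

#' @export
print.widefield_experiment <- function(x, ...) {
  cat(sprintf("Wide-field bundle: %d region(s) detected of %d simulated\n",
              nrow(x$regions), length(x$truth)))
  invisible(x)
}
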
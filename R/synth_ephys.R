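#' Synapse model for simulated EPSC trains
#'
#' Parameter container for the voltage-clamp generator.  Evoked AMPAR EPSCs
#' are modelled as peak-normalised difference-of-exponentials kernels riding
#' on a holding current, with short-term depression from a single-pool
#' vesicle-depletion recursion and a condition-dependent multiplicative gain
#' on amplitude (a postsynaptic effect: release parameters are shared across
#' conditions).
#'
#' @param base_amplitude first-pulse peak amplitude in the control condition,
#'   pA (> 0; stored as a magnitude, the simulated deflection is inward).
#' @param tau_rise,tau_decay kernel rise and decay time constants, ms
#'   (`tau_rise < tau_decay`).
#' @param release_fraction fraction of the releasable pool consumed per pulse
#'   (`0 < U <= 1`).
#' @param tau_recovery pool recovery time constant, ms.
#' @param condition_gain named numeric vector mapping condition labels to
#'   multiplicative amplitude factors (e.g. `c(control = 1, chelator = 0.75)`).
#' @param noise_sd additive white Gaussian noise sd, pA.  The default gives a
#'   first-pulse amplitude SNR of about 20.
#' @param holding_current baseline holding current, pA.
#' @return an object of class `synapse_model`.
#' @export
synapse_model <- function(base_amplitude = 100, tau_rise = 1, tau_decay = 15,
                          release_fraction = 0.4, tau_recovery = 200,
                          condition_gain = c(control = 1, chelator = 0.75),
                          noise_sd = base_amplitude / 20,
                          holding_current = -50) {
  stop_if(base_amplitude <= 0, "base_amplitude must be positive")
  stop_if(tau_rise >= tau_decay, "tau_rise must be smaller than tau_decay")
  stop_if(release_fraction <= 0 || release_fraction > 1,
          "release_fraction must lie in (0, 1]")
  stop_if(tau_recovery <= 0, "tau_recovery must be positive")
  stop_if(is.null(names(condition_gain)) || any(!nzchar(names(condition_gain))),
          "condition_gain must be a named vector")
  structure(list(base_amplitude = base_amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, release_fraction = release_fraction,
                 tau_recovery = tau_recovery, condition_gain = condition_gain,
                 noise_sd = noise_sd, holding_current = holding_current),
            class = "synapse_model")
}

#' @export
print.synapse_model <- function(x, ...) {
  cat(sprintf("Synapse model: A1 = %.1f pA, tau %.3g/%.3g ms, U = %.2f, tau_rec = %.3g ms\n",
              x$base_amplitude, x$tau_rise, x$tau_decay,
              x$release_fraction, x$tau_recovery))
  cat("  condition gains:",
      paste(sprintf("%s = %.3g", names(x$condition_gain), x$condition_gain),
            collapse = ", "), "\n")
  invisible(x)
}

#' Peak-normalised difference-of-exponentials EPSC kernel
#'
#' `k(t) = A (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_max`, zero at onset,
#' equal to `amplitude` at its peak
#' `t* = tau_rise tau_decay / (tau_decay - tau_rise) * log(tau_decay/tau_rise)`,
#' decaying with asymptotic time constant `tau_decay`.
#'
#' @param t time since pulse onset, ms (>= 0; negative values return 0).
#' @param tau_rise,tau_decay time constants, ms (`tau_rise < tau_decay`).
#' @param amplitude peak value, pA.
#' @return kernel values, same length as `t`.
#' @export
epsc_kernel <- function(t, tau_rise, tau_decay, amplitude = 1) {
  stop_if(tau_rise >= tau_decay, "tau_rise must be smaller than tau_decay")
  stop_if(tau_rise <= 0, "tau_rise must be positive")
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  k_max <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- amplitude * (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / k_max
  out
}

#' Vesicle-depletion amplitude profile along a pulse train
#'
#' Single-pool resource recursion: `R1 = 1`,
#' `R[n+1] = R[n] (1 - U) exp(-dt/tau_rec) + 1 - exp(-dt/tau_rec)`,
#' where `dt` is the interval between pulses n and n+1.  The per-pulse ideal
#' amplitude is `base_amplitude * gain * R[n]`.
#'
#' @param pulse_onsets pulse times, s, strictly increasing.
#' @param release_fraction U, fraction released per pulse.
#' @param tau_recovery recovery time constant, ms.
#' @return numeric vector `R[n]` of relative pool sizes, one per pulse.
#' @export
depletion_profile <- function(pulse_onsets, release_fraction, tau_recovery) {
  n <- length(pulse_onsets)
  stop_if(n < 1, "at least one pulse required")
  stop_if(n > 1 && any(diff(pulse_onsets) <= 0), "pulse onsets must be increasing")
  R <- numeric(n)
  R[1] <- 1
  if (n > 1) {
    dt_ms <- diff(pulse_onsets) * 1000
    for (i in seq_len(n - 1)) {
      e <- exp(-dt_ms[i] / tau_recovery)
      R[i + 1] <- R[i] * (1 - release_fraction) * e + 1 - e
    }
  }
  R
}

#' Simulate a voltage-clamp sweep with an evoked EPSC train
#'
#' Builds a current trace at `sample_rate` Hz: holding current plus an inward
#' (negative) EPSC kernel at each light-pulse onset, scaled by the depletion
#' recursion and the condition gain, plus additive white Gaussian noise.  The
#' noiseless per-pulse kernel amplitudes are returned as ground truth,
#' together with the baseline-referenced peak-to-trough amplitudes of the
#' noiseless superposition (what an ideal peak-to-trough measurement reads
#' when decay tails overlap the next pulse).
#'
#' @param model a [synapse_model()].
#' @param pulse_onsets light-pulse onset times, s, strictly increasing.
#' @param condition condition label; must name an entry of
#'   `model$condition_gain`.
#' @param seed integer seed for the noise stream (NULL for no reseeding).
#' @param sample_rate sampling rate, Hz.
#' @param sweep_duration total trace duration, s; default covers the last
#'   pulse plus 150 ms.
#' @param rs_log optional series-resistance log (MOhm) to attach; default a
#'   stable 15 MOhm log of 5 checks.
#' @return an object of class `sweep_recording`: list with `current` (pA),
#'   `time` (s), `sample_rate`, `pulse_onsets`, `condition`,
#'   `series_resistance_log`, and `ground_truth` (list: `amplitudes` ideal
#'   kernel amplitudes, `peak_to_trough` baseline-referenced noiseless
#'   measurements, `depletion` the recursion profile).
#' @export
simulate_epsc_train <- function(model, pulse_onsets, condition = "control",
                                seed = NULL, sample_rate = 10000,
                                sweep_duration = NULL, rs_log = NULL) {
  stopifnot(inherits(model, "synapse_model"))
  stop_if(!condition %in% names(model$condition_gain),
          "unknown condition label: ", condition)
  stop_if(length(pulse_onsets) > 1 && any(diff(pulse_onsets) <= 0),
          "pulse onsets must be strictly increasing")
  stop_if(sample_rate <= 0, "sample_rate must be positive")
  if (is.null(sweep_duration))
    sweep_duration <- max(pulse_onsets) + 0.15
  stop_if(max(pulse_onsets) >= sweep_duration,
          "pulse onsets must lie within the sweep duration")

  n_samp <- round(sweep_duration * sample_rate)
  tt <- (seq_len(n_samp) - 1) / sample_rate
  gain <- model$condition_gain[[condition]]
  R <- depletion_profile(pulse_onsets, model$release_fraction, model$tau_recovery)
  amps <- model$base_amplitude * gain * R

  clean <- rep(model$holding_current, n_samp)
  for (i in seq_along(pulse_onsets)) {
    t_ms <- (tt - pulse_onsets[i]) * 1000
    sel <- t_ms >= 0
    clean[sel] <- clean[sel] -
      epsc_kernel(t_ms[sel], model$tau_rise, model$tau_decay, amps[i])
  }

  # what an ideal peak-to-trough readout sees on the noiseless trace
  onset_idx <- pmin(n_samp, floor(pulse_onsets * sample_rate) + 1L)
  ipi <- if (length(pulse_onsets) > 1) min(diff(pulse_onsets)) else Inf
  win <- round(min(ipi, 0.1) * sample_rate)
  ptt <- vapply(seq_along(onset_idx), function(i) {
    i0 <- onset_idx[i]
    i1 <- min(n_samp, i0 + win)
    clean[i0] - min(clean[i0:i1])
  }, numeric(1))

  current <- clean
  if (model$noise_sd > 0)
    current <- current + with_seed(seed, stats::rnorm(n_samp, 0, model$noise_sd))

  if (is.null(rs_log)) rs_log <- rep(15, 5)
  structure(list(current = current, time = tt, sample_rate = sample_rate,
                 pulse_onsets = pulse_onsets, condition = condition,
                 series_resistance_log = rs_log,
                 ground_truth = list(amplitudes = amps, peak_to_trough = ptt,
                                     depletion = R)),
            class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("Voltage-clamp sweep: %.3g s at %g kHz, %d light pulse(s), condition '%s'\n",
              length(x$current) / x$sample_rate, x$sample_rate / 1000,
              length(x$pulse_onsets), x$condition))
  if (!is.null(x$ground_truth))
    cat("  ground-truth amplitudes (pA):",
        paste(sprintf("%.1f", x$ground_truth$amplitudes), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a series-resistance log
#'
#' Generates a monitoring log of `n_checks` resistance readings whose maximum
#' relative change from the first entry equals `drift_fraction` exactly
#' (linear ramp; noise-free mode), for exercising the QC exclusion rules.
#'
#' @param stable_value initial series resistance, MOhm (> 0).
#' @param drift_fraction total relative drift over the log (0 for constant).
#' @param n_checks number of readings (>= 2).
#' @param jitter_sd optional Gaussian jitter sd, MOhm (default 0).
#' @param seed seed for the jitter.
#' @return numeric vector of length `n_checks`, MOhm.
#' @export
simulate_rs_log <- function(stable_value, drift_fraction = 0, n_checks = 5,
                            jitter_sd = 0, seed = NULL) {
  stop_if(stable_value <= 0, "stable_value must be positive")
  stop_if(n_checks < 2, "n_checks must be at least 2")
  log <- stable_value * (1 + drift_fraction * seq(0, 1, length.out = n_checks))
  if (jitter_sd > 0)
    log <- log + with_seed(seed, stats::rnorm(n_checks, 0, jitter_sd))
  log
}

#' Write / read a simulated sweep as delimited text plus JSON sidecar
#'
#' The trace is written as a two-column (time_s, current_pA) tab-separated
#' file; sample rate, pulse onsets, condition, the series-resistance log and
#' any ground truth go to `<path>.json`.
#'
#' @param sweep a `sweep_recording`.
#' @param path path of the TSV trace file.
#' @return `path`, invisibly (`write_sweep`); a `sweep_recording`
#'   (`read_sweep`).
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_recording"))
  utils::write.table(
    data.frame(time_s = sweep$time, current_pA = sweep$current),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(list(sample_rate = sweep$sample_rate,
                     pulse_onsets = sweep$pulse_onsets,
                     condition = sweep$condition,
                     series_resistance_log = sweep$series_resistance_log,
                     ground_truth = sweep$ground_truth),
                paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  tab <- utils::read.delim(path)
  meta <- read_sidecar(paste0(path, ".json"))
  gt <- meta$ground_truth
  structure(list(current = tab$current_pA, time = tab$time_s,
                 sample_rate = meta$sample_rate,
                 pulse_onsets = as.numeric(meta$pulse_onsets),
                 condition = meta$condition,
                 series_resistance_log = as.numeric(meta$series_resistance_log),
                 ground_truth = if (is.null(gt)) NULL else
                   lapply(gt, as.numeric)),
            class = "sweep_recording")
}
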
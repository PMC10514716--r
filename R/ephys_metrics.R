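#' Average voltage-clamp sweeps of one condition
#'
#' Pointwise mean of 3-7 sweeps sharing sample rate, length, pulse onsets and
#' condition.  Amplitude metrics are computed on this averaged trace, not on
#' single trials.
#'
#' @param sweeps list of `sweep_recording` objects.
#' @param n_range allowed number of trials (default 3-7).
#' @param permissive if TRUE a trial count outside `n_range` only warns.
#' @return a `sweep_recording` holding the averaged trace.  The
#'   series-resistance logs are concatenated; ground truth is carried over
#'   from the first sweep (all sweeps of a condition share it).
#' @export
average_trials <- function(sweeps, n_range = c(3, 7), permissive = FALSE) {
  stop_if(length(sweeps) < 1, "no sweeps supplied")
  lapply(sweeps, function(s) stopifnot(inherits(s, "sweep_recording")))
  n <- length(sweeps)
  if (n < n_range[1] || n > n_range[2]) {
    msg <- sprintf("expected %d-%d trials, got %d", n_range[1], n_range[2], n)
    if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  ref <- sweeps[[1]]
  for (s in sweeps[-1]) {
    stop_if(length(s$current) != length(ref$current),
            "sweeps have mismatched trace lengths")
    stop_if(s$sample_rate != ref$sample_rate, "sweeps have mismatched sample rates")
    stop_if(!isTRUE(all.equal(s$pulse_onsets, ref$pulse_onsets)),
            "sweeps have mismatched pulse onsets")
    stop_if(!identical(s$condition, ref$condition),
            "sweeps have mismatched conditions")
  }
  avg <- rowMeans(vapply(sweeps, `[[`, numeric(length(ref$current)), "current"))
  structure(list(current = avg, time = ref$time, sample_rate = ref$sample_rate,
                 pulse_onsets = ref$pulse_onsets, condition = ref$condition,
                 series_resistance_log = unlist(lapply(sweeps, `[[`,
                                                       "series_resistance_log")),
                 ground_truth = ref$ground_truth, n_trials = n),
            class = "sweep_recording")
}

#' Per-pulse peak-to-trough EPSC amplitudes
#'
#' For each light pulse the amplitude is the difference between the current
#' at the start of the pulse (the baseline) and the most negative sample in
#' the post-pulse search window, reported as a positive magnitude (EPSCs are
#' inward at -70 mV).  The search window runs from the pulse onset to the
#' smaller of the inter-pulse interval and `max_window` (100 ms).
#'
#' @param sweep a `sweep_recording` (normally a trial average).
#' @param baseline_window length of the pre-onset window averaged to form the
#'   baseline, s.  Default 1 ms; `0` uses the single onset sample.
#' @param max_window cap on the peak-search window, s.
#' @return numeric vector of amplitudes, pA (magnitudes), one per pulse.
#' @export
measure_pulse_amplitudes <- function(sweep, baseline_window = 0.001,
                                     max_window = 0.1) {
  stopifnot(inherits(sweep, "sweep_recording"))
  onsets <- sweep$pulse_onsets
  stop_if(length(onsets) < 1, "sweep has no pulse onsets")
  fs <- sweep$sample_rate
  n <- length(sweep$current)
  ipi <- if (length(onsets) > 1) min(diff(onsets)) else Inf
  win <- round(min(ipi, max_window) * fs)
  vapply(seq_along(onsets), function(i) {
    i0 <- floor(onsets[i] * fs) + 1L
    stop_if(i0 > n, "pulse onset beyond trace end")
    stop_if(i0 + win > n,
            "peak-search window extends past the end of the trace")
    nb <- round(baseline_window * fs)
    b0 <- max(1L, i0 - nb)
    baseline <- mean(sweep$current[b0:i0])
    trough <- min(sweep$current[i0:(i0 + win)])
    abs(baseline - trough)
  }, numeric(1))
}

#' Fit a single-exponential decay time constant
#'
#' Fits `I(t) = baseline + a * exp(-(t - t_peak)/tau)` by Levenberg-Marquardt
#' least squares to the decay phase of one pulse's response, from the peak
#' sample to the end of the decay window (the next pulse onset or
#' `peak + 100 ms`, whichever is sooner).  Initialisation takes `tau0` as the
#' time for the response to fall to 1/e of its peak.
#'
#' @param sweep a `sweep_recording` (normally a trial average).
#' @param pulse_index which pulse to fit (default 1).
#' @param max_window decay window cap, s.
#' @param min_amplitude responses smaller than this (pA) are flagged as
#'   unfittable.
#' @return a list with `tau` (ms, or NA when flagged), `ok` (logical) and
#'   `reason` (character when not ok).
#' @export
fit_decay_tau <- function(sweep, pulse_index = 1, max_window = 0.1,
                          min_amplitude = 1) {
  stopifnot(inherits(sweep, "sweep_recording"))
  onsets <- sweep$pulse_onsets
  stop_if(pulse_index < 1 || pulse_index > length(onsets),
          "pulse_index out of range")
  fs <- sweep$sample_rate
  n <- length(sweep$current)
  i0 <- floor(onsets[pulse_index] * fs) + 1L
  t_end <- if (pulse_index < length(onsets))
    onsets[pulse_index + 1] else onsets[pulse_index] + max_window
  t_end <- min(t_end, onsets[pulse_index] + max_window)
  i1 <- min(n, floor(t_end * fs))
  seg <- sweep$current[i0:i1]

  # baseline from the 1 ms strictly before the pulse onset, so that decays
  # beginning at onset still register a peak and the fit's asymptote is the
  # resting current
  nb <- max(1L, round(0.001 * fs))
  baseline <- if (i0 > 1) mean(sweep$current[max(1L, i0 - nb):(i0 - 1L)])
    else seg[1]
  ipk <- which.min(seg)
  peak_amp <- baseline - seg[ipk]
  if (!is.finite(peak_amp) || peak_amp < min_amplitude)
    return(list(tau = NA_real_, ok = FALSE, reason = "no identifiable peak"))
  dec <- seg[ipk:length(seg)]
  if (length(dec) < 5)
    return(list(tau = NA_real_, ok = FALSE, reason = "decay segment too short"))

  t_ms <- (seq_along(dec) - 1) / fs * 1000
  y <- baseline - dec                       # positive, decaying toward 0
  i_e <- which(y <= y[1] / exp(1))[1]
  tau0 <- if (is.na(i_e)) max(t_ms) / 2 else max(t_ms[i_e], 1 / fs * 1000)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t_ms / tau), start = list(a = y[1], tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, ok = FALSE, reason = "fit did not converge"))
  tau <- unname(stats::coef(fit)[["tau"]])
  if (!is.finite(tau) || tau <= 0)
    return(list(tau = NA_real_, ok = FALSE, reason = "non-decaying segment"))
  list(tau = tau, ok = TRUE, reason = NULL)
}

#' Normalise an EPSC train against a control train
#'
#' Implements the five normalisation conventions used for paired
#' chelator-vs-control train comparisons:
#' \describe{
#'   \item{`first_vs_first`}{`test[1] / control[1]` (single value).}
#'   \item{`train_vs_first_control`}{`test[n] / control[1]`.}
#'   \item{`pointwise_vs_control`}{`test[n] / control[n]`.}
#'   \item{`mean_vs_mean`}{`mean(test) / mean(control)` (single value).}
#'   \item{`within_train`}{`test[n] / test[1]` (control ignored).}
#' }
#'
#' @param test,control amplitude vectors, pA (positive magnitudes).
#' @param scheme one of the scheme labels above.
#' @return an object of class `normalized_train`: list with `scheme`,
#'   `values` and `flagged` (logical, TRUE where a zero divisor made the
#'   value undefined).
#' @export
normalize_train <- function(test, control = test,
                            scheme = c("first_vs_first", "train_vs_first_control",
                                       "pointwise_vs_control", "mean_vs_mean",
                                       "within_train")) {
  scheme <- match.arg(scheme)
  vals <- switch(scheme,
    first_vs_first = test[1] / control[1],
    train_vs_first_control = test / control[1],
    pointwise_vs_control = {
      stop_if(length(test) != length(control),
              "pointwise scheme needs equal-length trains")
      test / control
    },
    mean_vs_mean = mean(test) / mean(control),
    within_train = test / test[1]
  )
  flagged <- !is.finite(vals)
  vals[flagged] <- NA_real_
  structure(list(scheme = scheme, values = unname(vals), flagged = flagged),
            class = "normalized_train")
}

#' @export
print.normalized_train <- function(x, ...) {
  cat(sprintf("Normalized train (%s): %s\n", x$scheme,
              paste(sprintf("%.3f", x$values), collapse = " ")))
  invisible(x)
}

#' Paired-pulse ratio
#'
#' `A2 / A1`, a presynaptic release-probability proxy.
#'
#' @param amplitudes per-pulse amplitudes, pA (>= 2 pulses).
#' @return list with `ppr` (NA when flagged) and `flagged`.
#' @export
paired_pulse_ratio <- function(amplitudes) {
  stop_if(length(amplitudes) < 2, "paired-pulse ratio needs at least 2 pulses")
  if (amplitudes[1] == 0)
    return(list(ppr = NA_real_, flagged = TRUE))
  list(ppr = amplitudes[2] / amplitudes[1], flagged = FALSE)
}

#' Relative steady state of a train
#'
#' Mean of the last `n_last` amplitudes divided by the first amplitude
#' (within-train convention).
#'
#' @param amplitudes per-pulse amplitudes, pA.
#' @param n_last number of terminal pulses averaged (default 3).
#' @return steady-state ratio, unitless.
#' @export
steady_state_ratio <- function(amplitudes, n_last = 3) {
  stop_if(length(amplitudes) <= n_last,
          "train must be longer than n_last (", n_last, ")")
  stop_if(amplitudes[1] == 0, "undefined: first amplitude is zero")
  mean(utils::tail(amplitudes, n_last)) / amplitudes[1]
}

#' Series-resistance quality control
#'
#' A recording fails QC if any series-resistance reading exceeds 30 MOhm, or
#' if any reading differs from the first by more than 15%.
#'
#' @param rs_log series-resistance readings, MOhm.
#' @param max_rs absolute ceiling, MOhm.
#' @param max_drift maximum allowed relative change from the first reading.
#' @return list with `pass` (logical) and `reason` (character; "ok" on pass,
#'   otherwise names the rule that fired).
#' @export
qc_series_resistance <- function(rs_log, max_rs = 30, max_drift = 0.15) {
  stop_if(length(rs_log) < 1, "empty series-resistance log")
  stop_if(any(rs_log <= 0), "series resistance must be positive")
  if (any(rs_log > max_rs))
    return(list(pass = FALSE,
                reason = sprintf("series resistance above %g MOhm (max %.1f)",
                                 max_rs, max(rs_log))))
  drift <- max(abs(rs_log - rs_log[1]) / rs_log[1])
  if (drift > max_drift)
    return(list(pass = FALSE,
                reason = sprintf("series resistance changed more than %.0f%% (%.1f%%)",
                                 100 * max_drift, 100 * drift)))
  list(pass = TRUE, reason = "ok")
}

#' Full EPSC train quantification for one averaged sweep
#'
#' Convenience wrapper: amplitudes, first-pulse decay tau, paired-pulse
#' ratio, steady-state ratio and series-resistance QC in one object.
#'
#' @param avg_sweep an averaged `sweep_recording`.
#' @param n_last terminal pulses for the steady-state ratio.
#' @param ... passed to [measure_pulse_amplitudes()].
#' @return an object of class `epsc_metrics`.
#' @export
epsc_train_metrics <- function(avg_sweep, n_last = 3, ...) {
  amps <- measure_pulse_amplitudes(avg_sweep, ...)
  np <- length(amps)
  tau <- fit_decay_tau(avg_sweep, 1)
  structure(list(
    amplitudes = amps,
    decay_tau = tau$tau,
    decay_ok = tau$ok,
    ppr = if (np >= 2) paired_pulse_ratio(amps)$ppr else NA_real_,
    steady_state = if (np > n_last) steady_state_ratio(amps, n_last) else NA_real_,
    qc = qc_series_resistance(avg_sweep$series_resistance_log),
    condition = avg_sweep$condition
  ), class = "epsc_metrics")
}

#' @export
print.epsc_metrics <- function(x, ...) {
  cat(sprintf("EPSC train metrics (condition '%s'):\n", x$condition))
  cat("  amplitudes (pA):", paste(sprintf("%.1f", x$amplitudes), collapse = " "), "\n")
  cat(sprintf("  decay tau: %s ms | PPR: %s | steady state: %s | QC: %s\n",
              ifelse(is.na(x$decay_tau), "NA", sprintf("%.1f", x$decay_tau)),
              ifelse(is.na(x$ppr), "NA", sprintf("%.2f", x$ppr)),
              ifelse(is.na(x$steady_state), "NA", sprintf("%.2f", x$steady_state)),
              ifelse(x$qc$pass, "pass", paste0("FAIL (", x$qc$reason, ")"))))
  invisible(x)
}
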
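# Shared fixtures: all built in code, no stored data.

default_block <- function(seed = 1L) build_tone_block(seed = seed)

# a neuron whose band edges land exactly on the 1/8-octave grid
clean_rf_model <- function(threshold_true = 50, ...) {
  receptive_field_model(bf_true = 10000, threshold_true = threshold_true,
                        noise_sd = 0, amp_jitter_sdlog = 0, ...)
}

# hand-built sweep container for synthetic trace fixtures
make_sweep <- function(current, sample_rate, pulse_onsets,
                       condition = "control", rs_log = rep(15, 5)) {
  structure(list(current = current,
                 time = (seq_along(current) - 1) / sample_rate,
                 sample_rate = sample_rate, pulse_onsets = pulse_onsets,
                 condition = condition, series_resistance_log = rs_log,
                 ground_truth = NULL),
            class = "sweep_recording")
}

# hand-built tuning surface for metric edge cases
make_surface <- function(peak_z, responsive, frequencies, levels) {
  structure(list(peak_z = peak_z, responsive = responsive,
                 frequencies = frequencies, levels = levels,
                 avg_dff = NULL, repeat_windows = NULL,
                 repeats_used = 5L, flagged = FALSE),
            class = "tuning_surface")
}

# closed-form steady state of the single-pool depletion recursion
closed_form_rss <- function(U, tau_rec_ms, dt_ms) {
  e <- exp(-dt_ms / tau_rec_ms)
  (1 - e) / (1 - (1 - U) * e)
}
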
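#' Build a pseudorandom tone-presentation block
#'
#' Constructs the frequency x level stimulus grid used for frequency-response
#' area mapping and arranges one presentation of every unique (frequency,
#' level) combination in a seeded pseudorandom order with fixed inter-stimulus
#' timing.  The defaults reproduce the standard awake-imaging block: 5-40 kHz
#' in 1/8-octave steps at 40-80 dB SPL (125 combinations), 500 ms tones with
#' 20 ms cosine ramps and 3 s inter-stimulus intervals.
#'
#' The frequency grid is `f_min * 2^(k * octave_step)` for `k = 0..K`, with
#' `K = round(log2(f_max/f_min) / octave_step)` so that a 5-40 kHz range at
#' 1/8 octave lands exactly on 40 kHz.  If the range is not an integer number
#' of steps the grid includes the largest frequency `<= f_max`.
#'
#' "Pseudorandom" is a seeded uniform shuffle: identical seeds give identical
#' orders, and the multiset of stimuli never depends on the seed.
#'
#' @param f_min,f_max lowest and highest tone frequency, Hz.
#' @param octave_step grid spacing in octaves (> 0).
#' @param levels sound levels, dB SPL.
#' @param duration tone duration, s.
#' @param ramp onset/offset ramp, s (`0 <= ramp <= duration/2`).
#' @param isi inter-stimulus interval (offset to next onset), s.
#' @param seed integer seed for the presentation order.
#' @param t_start onset time of the first stimulus, s.
#' @return an object of class `stim_block`: a list with `stimuli` (data.frame
#'   with columns `index`, `frequency_hz`, `level_db`, `onset_s`,
#'   `duration_s`, `ramp_s`), `frequencies`, `levels`, `isi`, `duration`,
#'   `ramp`, `seed`, `t_start` and `n_unique`.
#' @examples
#' blk <- build_tone_block(seed = 1)
#' blk$n_unique                       # 125
#' length(blk$frequencies)            # 25
#' @export
build_tone_block <- function(f_min = 5000, f_max = 40000, octave_step = 1 / 8,
                             levels = c(40, 50, 60, 70, 80),
                             duration = 0.5, ramp = 0.02, isi = 3,
                             seed = 1L, t_start = 0) {
  stop_if(!is.numeric(f_min) || f_min <= 0, "f_min must be positive (got ", f_min, ")")
  stop_if(!is.numeric(f_max) || f_max <= 0, "f_max must be positive (got ", f_max, ")")
  stop_if(f_min > f_max, "f_min must not exceed f_max")
  stop_if(octave_step <= 0, "octave_step must be positive (got ", octave_step, ")")
  stop_if(length(levels) < 1, "levels must be non-empty")
  stop_if(duration <= 0, "duration must be positive (got ", duration, ")")
  stop_if(ramp < 0 || ramp > duration / 2, "ramp must satisfy 0 <= ramp <= duration/2")
  stop_if(isi < 0, "isi must be non-negative (got ", isi, ")")

  freqs <- tone_frequency_grid(f_min, f_max, octave_step)
  grid <- expand.grid(frequency_hz = freqs, level_db = sort(levels),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  ord <- with_seed(seed, sample.int(n))
  grid <- grid[ord, , drop = FALSE]
  grid$index <- seq_len(n)
  grid$onset_s <- t_start + (seq_len(n) - 1) * (duration + isi)
  grid$duration_s <- duration
  grid$ramp_s <- ramp
  rownames(grid) <- NULL
  structure(list(
    stimuli = grid[, c("index", "frequency_hz", "level_db", "onset_s",
                       "duration_s", "ramp_s")],
    frequencies = freqs, levels = sort(levels),
    isi = isi, duration = duration, ramp = ramp,
    seed = as.integer(seed), t_start = t_start, n_unique = n
  ), class = "stim_block")
}

#' Tone frequency grid in octave steps
#'
#' @inheritParams build_tone_block
#' @return numeric vector of frequencies in Hz, ascending.
#' @export
tone_frequency_grid <- function(f_min, f_max, octave_step) {
  stop_if(f_min <= 0, "f_min must be positive (got ", f_min, ")")
  stop_if(octave_step <= 0, "octave_step must be positive (got ", octave_step, ")")
  if (f_min == f_max) return(f_min)
  span <- log2(f_max / f_min)
  K <- round(span / octave_step)
  # rounding may overshoot f_max; keep the largest grid point <= f_max
  # (with slack for floating-point landing exactly on f_max)
  k <- 0:K
  f <- f_min * 2^(k * octave_step)
  f[f <= f_max * (1 + 1e-9)]
}

#' @export
print.stim_block <- function(x, ...) {
  cat("Tone stimulus block:", x$n_unique, "unique frequency x level combinations\n")
  cat(sprintf("  %d frequencies, %.1f-%.1f kHz (%.3g octaves); levels %s dB SPL\n",
              length(x$frequencies), min(x$frequencies) / 1000,
              max(x$frequencies) / 1000,
              log2(max(x$frequencies) / min(x$frequencies)),
              paste(x$levels, collapse = "/")))
  cat(sprintf("  %.0f ms tones, %.0f ms ramps, %.1f s ISI; seed %d\n",
              x$duration * 1000, x$ramp * 1000, x$isi, x$seed))
  invisible(x)
}

#' Write / read a stimulus block as delimited text plus JSON sidecar
#'
#' The block's presentation table is written as a tab-separated file and its
#' grid parameters (seed, ISI, duration, ramp, frequency grid, levels) to
#' `<path>.json`, so that `read_stim_block()` recovers an identical block.
#'
#' @param block a `stim_block`.
#' @param path path of the TSV table; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly (`write_stim_block`); a `stim_block`
#'   (`read_stim_block`).
#' @export
write_stim_block <- function(block, path) {
  stopifnot(inherits(block, "stim_block"))
  utils::write.table(block$stimuli, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sidecar(list(seed = block$seed, isi = block$isi,
                     duration = block$duration, ramp = block$ramp,
                     t_start = block$t_start,
                     frequencies = block$frequencies, levels = block$levels),
                paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_stim_block
#' @export
read_stim_block <- function(path) {
  tab <- utils::read.delim(path)
  meta <- read_sidecar(paste0(path, ".json"))
  structure(list(
    stimuli = tab,
    frequencies = as.numeric(meta$frequencies), levels = as.numeric(meta$levels),
    isi = meta$isi, duration = meta$duration, ramp = meta$ramp,
    seed = as.integer(meta$seed), t_start = meta$t_start,
    n_unique = nrow(tab)
  ), class = "stim_block")
}
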
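#' Derive a child seed from a master seed
#'
#' Deterministically spawns per-stage seeds from a master seed so that each
#' stochastic stage of a pipeline can be rerun in isolation.  Uses a
#' Lehmer-style multiplicative congruence modulo 2^31 - 1, so derived seeds
#' always fit in a 32-bit R integer.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0); distinct stages give distinct
#'   seed streams.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(stage) * 3819 + 1) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @keywords internal
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @keywords internal
read_sidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
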
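#' Derive a child seed from a master seed
#'
#' All randomized stages of the pipeline draw their own seed from one master
#' seed through this splitting rule, so that any stage can be re-run in
#' isolation and reproduce its output bit-exactly. The rule is a fixed affine
#' hash of the master seed, a stage tag and an index, reduced modulo
#' 2^31 - 1 so the result is always a valid 32-bit integer seed.
#'
#' @param seed master seed (integer)
#' @param tag character stage tag, e.g. "simulate", "folds"
#' @param index integer index within the stage (e.g. subject number)
#' @return an integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, tag = "stage", index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271) %% m
  x <- (x + h * 69621 + as.numeric(index) * 16807) %% m
  as.integer(x %% (m - 2L) + 1L)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded internals do not
#' disturb the caller's RNG stream.
#' @param seed integer seed, or NULL to leave the RNG stream untouched
#' @param expr expression to evaluate
#' @return the value of \code{expr}
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

# index of samples falling inside a closed time window
window_index <- function(times_ms, window_ms) {
  stopifnot(length(window_ms) == 2L, window_ms[2] >= window_ms[1])
  idx <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (length(idx) == 0L)
    stop("time window [", window_ms[1], ", ", window_ms[2],
         "] ms contains no samples", call. = FALSE)
  idx
}
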
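# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded calls do not perturb a caller's stream.
#' With `seed = NULL` the code runs on the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a base seed
#'
#' Deterministic 31-bit mix so that pipeline stages each get an independent,
#' reproducible seed from one user-supplied base seed.
#'
#' @param base integer base seed.
#' @param offset integer stage offset.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, offset = 0L) {
  m <- 2147483647
  x <- (as.numeric(base) %% m) * 48271 + as.numeric(offset) * 8191 + 1
  as.integer(x %% (m - 1) + 1)
}

# stderr logging with a machine-readable prefix (stage, counts).
log_msg <- function(stage, ...) {
  message(sprintf("[bsamap:%s] %s", stage, paste0(...)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)
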
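#' Run code with a local RNG state
#'
#' Evaluates `expr` with the random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that library code never
#' perturbs user-level reproducibility.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)  # materialise .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into per-stage seeds, kept inside
# the 32-bit integer range R requires.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offs <- sum(utf8ToInt(as.character(stage))) * 10007L
  as.integer((as.numeric(master) * 48271 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
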
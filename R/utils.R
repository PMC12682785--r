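#' Evaluate an expression under a local RNG state
#'
#' Runs \code{expr} with the RNG seeded at \code{seed}, then restores the
#' caller's RNG state, so seeded package functions never perturb the global
#' random stream. With \code{seed = NULL} the expression runs on the current
#' stream (no save/restore).
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, keeping the result
# a valid 32-bit integer. Distinct labels give independent streams so that,
# e.g., changing the CV seed never touches the bootstrap draws.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || is.na(x)) stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  invisible(x)
}
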
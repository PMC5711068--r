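#' @keywords internal
"_PACKAGE"

# Run `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_imrtqa <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_imrtqa(what, " must be finite numeric")
  invisible(x)
}

# Relative equality used by MU-consistency invariants.
rel_equal <- function(a, b, tol = 1e-9) {
  denom <- max(abs(a), abs(b), 1e-300)
  abs(a - b) / denom <= tol
}
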
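# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' stream so library code does not clobber user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' @noRd
assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

#' Clip values to an interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a bounded child seed from a parent seed and a stream label, so that
# independent random streams can be spawned from one user-facing seed.
#' @noRd
child_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + as.numeric(stream) * 7919) %% 2147483587)
}
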
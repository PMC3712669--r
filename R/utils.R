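#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (and advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible per-unit sub-seed from a base seed, so unit i gives
# the same stream no matter which units are run or in what order.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 7919 * as.double(index)) %% (2^31 - 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

stopifnot_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) || anyNA(x) ||
    any(if (lo_open) x <= lo else x < lo) ||
    any(if (hi_open) x >= hi else x > hi)
  if (bad) {
    stop(sprintf(
      "`%s` must lie in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ), call. = FALSE)
  }
}
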
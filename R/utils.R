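# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-unit substream seed below 2^31, mixing a base seed with a
# unit index (voxel, subject, session ...). Splitmix-style integer hash.
derive_seed <- function(seed, index) {
  x <- (as.double(seed) * 2654435761 + as.double(index) * 40503 + 1013904223)
  as.integer(x %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x))
  }
  invisible(x)
}

is_finite_vector <- function(x) is.numeric(x) && all(is.finite(x))
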
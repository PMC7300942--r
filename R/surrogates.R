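# Iterative amplitude-adjusted Fourier transform (iAAFT) surrogates.

#' iAAFT surrogate of a series
#'
#' Produces a linearised copy of the input whose sorted values equal the
#' original's sorted values exactly (rank remapping) and whose amplitude
#' spectrum converges to the original's over the iterations. Starting from
#' a seeded random permutation, each iteration (i) imposes the original
#' amplitude spectrum keeping current phases, then (ii) rank-remaps onto
#' the original value distribution. Iteration stops early once the rank
#' ordering is stable, which is a fixed point of the scheme.
#'
#' @param x Numeric series, length >= 64.
#' @param n_iterations Maximum iterations (default 100).
#' @param seed Integer seed; the same seed gives an identical surrogate.
#'   The caller's RNG state is left untouched.
#' @return Numeric surrogate series of the same length.
#' @export
iaaft_surrogate <- function(x, n_iterations = 100L, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 64L) abort("series too short for surrogate generation (need N >= 64)")
  if (!is_finite_vector(x)) abort("series contains non-finite values")
  amp_sorted <- sort(x)
  target_mod <- Mod(fft(x))
  s <- with_seed(seed, x[sample.int(n)])
  prev_ord <- integer(0)
  for (it in seq_len(n_iterations)) {
    ft <- fft(s)
    md <- Mod(ft)
    md[md == 0] <- 1
    # keep phases, impose the original amplitude spectrum
    s2 <- Re(fft(target_mod * (ft / md), inverse = TRUE) / n)
    o <- order(s2)
    s[o] <- amp_sorted
    # unchanged ordering is an exact fixed point: further iterations
    # reproduce the same series, so stopping early changes nothing
    if (identical(o, prev_ord)) break
    prev_ord <- o
  }
  s
}

# Batch iAAFT: all surrogates iterated in lockstep via mvfft, each column
# frozen at its own rank fixed point (or n_iterations). Column j is
# identical to iaaft_surrogate(x, n_iterations, derive_seed(seed, j)).
iaaft_surrogates <- function(x, n_surrogates, n_iterations = 100L, seed = 1L) {
  n <- length(x)
  amp_sorted <- sort(x)
  target_mod <- Mod(fft(x))
  s <- vapply(seq_len(n_surrogates),
              function(j) with_seed(derive_seed(seed, j), x[sample.int(n)]),
              numeric(n))
  prev_ord <- vector("list", n_surrogates)
  active <- rep(TRUE, n_surrogates)
  for (it in seq_len(n_iterations)) {
    ft <- stats::mvfft(s[, active, drop = FALSE])
    md <- Mod(ft)
    md[md == 0] <- 1
    s2 <- Re(stats::mvfft(target_mod * (ft / md), inverse = TRUE) / n)
    which_active <- which(active)
    for (cc in seq_along(which_active)) {
      j <- which_active[cc]
      o <- order(s2[, cc])
      s[o, j] <- amp_sorted
      if (identical(o, prev_ord[[j]])) active[j] <- FALSE
      prev_ord[[j]] <- o
    }
    if (!any(active)) break
  }
  s
}
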
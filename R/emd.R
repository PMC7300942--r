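# Empirical mode decomposition by cubic-spline envelope sifting.

# Interior local extrema; flat segments yield a single extremum at the
# middle of the flat. Returns 1-based sample indices.
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  idx <- which(s != 0)
  if (length(idx) < 2L) return(list(maxima = integer(), minima = integer()))
  ss <- s[idx]
  ch <- which(diff(ss) != 0)
  if (!length(ch)) return(list(maxima = integer(), minima = integer()))
  # slope idx[c] ends at sample idx[c]+1; opposite slope resumes at idx[c+1];
  # place the extremum at the middle of any intervening flat
  at <- ((idx[ch] + 1L) + idx[ch + 1L]) %/% 2L
  list(maxima = at[ss[ch] > 0], minima = at[ss[ch] < 0])
}

# Cubic-spline envelope through extrema with 2-point mirror extension at
# each boundary, evaluated at all n samples.
spline_envelope <- function(t, v, n) {
  k <- min(2L, length(t))
  m <- length(t)
  tt <- c(2 - t[k:1], t, 2 * n - t[m:(m - k + 1L)])
  vv <- c(v[k:1], v, v[m:(m - k + 1L)])
  keep <- !duplicated(tt)
  stats::splinefun(tt[keep], vv[keep], method = "fmm")(seq_len(n))
}

envelope_mean <- function(x, ext) {
  n <- length(x)
  upper <- spline_envelope(ext$maxima, x[ext$maxima], n)
  lower <- spline_envelope(ext$minima, x[ext$minima], n)
  (upper + lower) / 2
}

#' Empirical mode decomposition
#'
#' Sifts a series into intrinsic mode functions (IMFs) `c_1 ... c_M` and a
#' residual `r_M` with `x = sum(c_j) + r_M` holding exactly by construction.
#' Sifting uses cubic-spline envelopes through the extrema (mirror-extended
#' by two extrema at each end) and the standard-deviation stopping rule
#' `sum((h_prev - h_cur)^2) / sum(h_prev^2) < sd_thresh` per sift.
#' Decomposition stops when the residual has at most one interior extremum
#' (a strictly monotone input therefore yields zero IMFs) or `max_imf` is
#' reached.
#'
#' @param x Numeric series, length >= 64, non-constant.
#' @param sd_thresh Sifting stop threshold (default 0.2).
#' @param max_sift Maximum sifts per IMF (default 100).
#' @param max_imf Maximum number of IMFs (default 12).
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors), `residual`, and the original `input`.
#' @export
emd <- function(x, sd_thresh = 0.2, max_sift = 100L, max_imf = 12L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 64L) abort("signal too short for EMD (need N >= 64)")
  if (!is_finite_vector(x)) abort("signal contains non-finite values")
  if (var(x) < 1e-12 * mean(x^2) || all(x == x[1])) abort("degenerate signal: (near-)constant input")
  residual <- x
  imfs <- list()
  while (length(imfs) < max_imf) {
    ext <- local_extrema(residual)
    if (length(ext$maxima) + length(ext$minima) <= 1L) break
    h <- residual
    for (s in seq_len(5L * max_sift)) {
      ext_h <- local_extrema(h)
      # one extremum of a type still gives 3 spline knots after mirroring
      if (length(ext_h$maxima) < 1L || length(ext_h$minima) < 1L) break
      m <- envelope_mean(h, ext_h)
      sd_val <- sum(m^2) / sum(h^2)
      h <- h - m
      # stop once the envelope correction is small AND the IMF condition
      # (extrema and zero-crossing counts differing by at most one) holds;
      # past the soft sift cap the condition alone suffices, with a hard
      # cap at five times the soft cap
      if ((sd_val < sd_thresh || s > max_sift) && imf_property_ok(h)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  structure(list(imfs = imfs, residual = residual, input = x), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, N = %d\n",
              length(x$imfs), length(x$input)))
  invisible(x)
}

#' @rdname emd
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return `tidy.imf_set()`: long tibble with `component` ("imf1" ...,
#'   "residual"), `time`, `value`.
#' @method tidy imf_set
#' @export
tidy.imf_set <- function(x, ...) {
  comps <- c(stats::setNames(x$imfs, paste0("imf", seq_along(x$imfs))),
             list(residual = x$residual))
  purrr::imap_dfr(comps, function(v, nm) {
    tibble(component = nm, time = seq_along(v), value = v)
  })
}

# |#extrema - #zero-crossings| <= 1, the defining IMF property
imf_property_ok <- function(v) {
  ext <- local_extrema(v)
  n_ext <- length(ext$maxima) + length(ext$minima)
  sgn <- sign(v)
  sgn <- sgn[sgn != 0]
  n_zc <- sum(diff(sgn) != 0)
  abs(n_ext - n_zc) <= 1L
}
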
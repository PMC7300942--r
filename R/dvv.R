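# Delay vector variance (DVV) analysis and the degree of non-linearity (DN).

#' Delay embedding of a series
#'
#' Builds the `N - m` delay vectors `x(k) = [x_{k-m}, ..., x_{k-1}]` with
#' their targets `x_k` (the next sample).
#'
#' @param x Numeric series of length N > m.
#' @param m Embedding dimension (>= 1).
#' @return Object of class `delay_embedding`: list with `dvs` (`(N-m) x m`
#'   matrix), `targets`, `m`.
#' @export
delay_embed <- function(x, m) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  if (m < 1L) abort("`m` must be >= 1")
  if (n <= m) abort(sprintf("series length (%d) must exceed embedding dimension (%d)", n, m))
  ndv <- n - m
  dvs <- matrix(0, ndv, m)
  for (t in seq_len(m)) dvs[, t] <- x[seq.int(t, t + ndv - 1L)]
  structure(list(dvs = dvs, targets = x[seq.int(m + 1L, n)], m = m),
            class = "delay_embedding")
}

#' Pairwise distance profile of a delay embedding
#'
#' Mean and population standard deviation over all unordered pairwise
#' Euclidean distances between delay vectors; these standardise the DVV
#' span grid.
#'
#' @param emb A [delay_embed()] result.
#' @return List with `mu_d` and `sd_d`.
#' @export
distance_profile <- function(emb) {
  if (!inherits(emb, "delay_embedding")) abort("`emb` must be a delay_embedding")
  if (nrow(emb$dvs) < 2L) abort("need at least 2 delay vectors")
  d <- as.numeric(stats::dist(emb$dvs))
  list(mu_d = mean(d), sd_d = sqrt(mean((d - mean(d))^2)))
}

#' DVV parameter bundle
#'
#' Established delay-vector-variance practice: embedding dimension 3, span
#' parameter 3, 25 uniformly spaced spans, minimum neighbourhood size 30,
#' and 25 iAAFT surrogates of at most 100 iterations each.
#'
#' @param m Embedding dimension.
#' @param n_d Span half-width in pairwise-distance standard deviations.
#' @param n_spans Number of uniformly spaced span thresholds.
#' @param t0 Minimum retained neighbourhood size (>= 2).
#' @param n_surrogates Number of iAAFT surrogates.
#' @param n_iterations Maximum iAAFT iterations per surrogate.
#' @return Named list of parameters.
#' @export
dvv_params <- function(m = 3L, n_d = 3, n_spans = 25L, t0 = 30L,
                       n_surrogates = 25L, n_iterations = 100L) {
  if (t0 < 2L) abort("`t0` must be >= 2 (target variance needs 2 members)")
  list(m = as.integer(m), n_d = n_d, n_spans = as.integer(n_spans),
       t0 = as.integer(t0), n_surrogates = as.integer(n_surrogates),
       n_iterations = as.integer(n_iterations))
}

#' DVV target-variance curve
#'
#' The series is standardised internally (zero mean, unit variance) so span
#' thresholds are comparable across voxels. For each span `tau` over
#' `[max(0, mu_d - n_d*sd_d), mu_d + n_d*sd_d]`, the neighbourhood of each
#' delay vector gathers all delay vectors within `tau`; neighbourhoods
#' smaller than `t0` are discarded, and `sigma_star(tau)` is the mean over
#' retained neighbourhoods of the target variance normalised by the series
#' variance. Spans retaining no neighbourhood are marked invalid.
#'
#' @param x Numeric series with positive variance.
#' @param m,n_d,n_spans,t0 See [dvv_params()].
#' @return Tibble with columns `span`, `sigma_star`, `valid`, and
#'   attributes `mu_d`, `sd_d`.
#' @export
dvv_curve <- function(x, m = 3L, n_d = 3, n_spans = 25L, t0 = 30L) {
  x <- as.numeric(x)
  if (!is_finite_vector(x)) abort("series contains non-finite values")
  if (length(x) <= m + 1L) abort("series too short for the embedding")
  if (n_spans < 2L) abort("`n_spans` must be >= 2")
  if (t0 < 2L) abort("`t0` must be >= 2")
  res <- dvv_sigma(x, m, n_d, n_spans, t0)
  out <- tibble(span = res$spans, sigma_star = res$sigma_star,
                valid = res$valid)
  attr(out, "mu_d") <- res$mu_d
  attr(out, "sd_d") <- res$sd_d
  attr(out, "sigma_x2") <- res$sigma_x2
  out
}

# standardise and run the compiled DVV kernel (no tibble overhead)
dvv_sigma <- function(x, m, n_d, n_spans, t0) {
  s <- sd(x)
  if (s == 0) abort("constant series: variance is zero")
  xs <- (x - mean(x)) / s
  dvv_curve_cpp(xs, as.integer(m), n_d, as.integer(n_spans), as.integer(t0))
}

rmse_over <- function(a, b, ok) {
  sqrt(mean((a[ok] - b[ok])^2))
}

#' Degree of non-linearity via DVV surrogate comparison
#'
#' Computes the DVV curve of the series and of `n_surrogates` iAAFT
#' surrogates (linearised copies preserving amplitude distribution and,
#' approximately, the spectrum). DN is the root mean square error between
#' the original curve and the surrogate-averaged curve over spans valid in
#' both; the per-surrogate deviations from the same average form the null
#' for traditional right-tailed surrogate testing.
#'
#' @param x Numeric series (length >= 64 for surrogate generation).
#' @param params A [dvv_params()] list.
#' @param seed Integer seed; surrogate `s` uses a substream derived from
#'   `(seed, s)`, so results are fully reproducible.
#' @return Object of class `dvv_result`: list with `curve` (tibble: `span`,
#'   `sigma_star`, `surrogate_mean`, `valid`), `surrogates` (span x
#'   surrogate matrix), `dn`, `null_rmse`, `p_value`, `n_valid_spans`,
#'   `mu_d`, `sd_d`, `params`, `seed`.
#' @export
degree_of_nonlinearity <- function(x, params = dvv_params(), seed = 1L) {
  orig <- dvv_curve(x, params$m, params$n_d, params$n_spans, params$t0)
  surr <- matrix(NA_real_, params$n_spans, params$n_surrogates)
  surr_series <- iaaft_surrogates(x, params$n_surrogates,
                                  n_iterations = params$n_iterations,
                                  seed = seed)
  for (s in seq_len(params$n_surrogates)) {
    cs <- dvv_sigma(surr_series[, s], params$m, params$n_d, params$n_spans,
                    params$t0)
    surr[, s] <- ifelse(cs$valid, cs$sigma_star, NA_real_)
  }
  n_ok <- rowSums(!is.na(surr))
  avg <- ifelse(n_ok > 0, rowMeans(surr, na.rm = TRUE), NA_real_)
  ok <- orig$valid & n_ok > 0
  if (!any(ok)) abort("DVV curves incomparable: no jointly valid spans")
  dn <- rmse_over(orig$sigma_star, avg, ok)
  null_rmse <- vapply(seq_len(params$n_surrogates), function(s) {
    ok_s <- !is.na(surr[, s]) & !is.na(avg)
    if (!any(ok_s)) return(NA_real_)
    rmse_over(surr[, s], avg, ok_s)
  }, numeric(1))
  p_value <- (1 + sum(null_rmse >= dn, na.rm = TRUE)) /
    (1 + sum(!is.na(null_rmse)))
  curve <- tibble(span = orig$span, sigma_star = orig$sigma_star,
                  surrogate_mean = avg, valid = ok)
  structure(list(curve = curve, surrogates = surr, dn = dn,
                 null_rmse = null_rmse, p_value = p_value,
                 n_valid_spans = sum(ok), mu_d = attr(orig, "mu_d"),
                 sd_d = attr(orig, "sd_d"), params = params, seed = seed),
            class = "dvv_result")
}

#' @export
print.dvv_result <- function(x, ...) {
  cat(sprintf("<dvv_result> DN = %.4g over %d valid spans (%d surrogates, p = %.3f)\n",
              x$dn, x$n_valid_spans, x$params$n_surrogates, x$p_value))
  invisible(x)
}

#' @rdname degree_of_nonlinearity
#' @param x A `dvv_result`.
#' @param ... Unused.
#' @method tidy dvv_result
#' @export
tidy.dvv_result <- function(x, ...) x$curve

#' @rdname degree_of_nonlinearity
#' @method glance dvv_result
#' @export
glance.dvv_result <- function(x, ...) {
  tibble(dn = x$dn, p_value = x$p_value, n_valid_spans = x$n_valid_spans,
         n_surrogates = x$params$n_surrogates)
}

#' Voxel-wise DN map
#'
#' Applies [degree_of_nonlinearity()] to every row of an [fmri_series()].
#' Per-voxel surrogate seeds are derived deterministically from
#' `(seed, voxel index)`, so the map is reproducible and independent of
#' evaluation order. Degenerate voxels are `NA`; more than 50% aborts.
#'
#' @param series An [fmri_series()].
#' @param params A [dvv_params()] list.
#' @param seed Integer base seed.
#' @return Tibble with `voxel`, `i`, `j`, `k`, `dn`, `n_valid_spans`,
#'   `p_surrogate`.
#' @export
dn_map <- function(series, params = dvv_params(), seed = 1L) {
  if (!inherits(series, "fmri_series")) abort("`series` must be an fmri_series")
  v <- nrow(series$values)
  dn <- p <- rep(NA_real_, v)
  nvs <- rep(NA_integer_, v)
  for (r in seq_len(v)) {
    res <- tryCatch(
      degree_of_nonlinearity(series$values[r, ], params,
                             seed = derive_seed(seed, r)),
      error = function(e) NULL)
    if (!is.null(res)) {
      dn[r] <- res$dn
      p[r] <- res$p_value
      nvs[r] <- res$n_valid_spans
    }
  }
  n_bad <- sum(is.na(dn))
  if (n_bad > v / 2) abort(sprintf("DN map aborted: %d of %d voxels degenerate", n_bad, v))
  if (n_bad > 0) inform(sprintf("%d of %d voxels degenerate (DN = NA)", n_bad, v))
  dplyr::bind_cols(voxel_coords(series$geometry),
                   tibble(dn = dn, n_valid_spans = nvs, p_surrogate = p))
}
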
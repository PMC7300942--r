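# Hilbert spectral analysis and the degree of stationarity (DS).

phase_unwrap <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Analytic signal of an IMF
#'
#' Hilbert transform via the FFT one-sided-spectrum method, giving the
#' instantaneous amplitude `a(n)` and instantaneous frequency `w(n)` in
#' cycles/sample. The frequency is the centred difference of the unwrapped
#' analytic phase divided by 2*pi (one-sided at the endpoints); negative
#' estimates are clipped to 0 and flagged invalid (excluded from spectral
#' binning), and values are capped at Nyquist (0.5).
#'
#' @param imf Numeric vector, length >= 4.
#' @return Object of class `analytic_imf`: list with `amplitude`, `phase`
#'   (unwrapped radians), `inst_freq` (cycles/sample, clipped to the
#'   Nyquist range), and `freq_valid` (logical).
#' @export
analytic_signal <- function(imf) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 4L) abort("IMF too short (need length >= 4)")
  if (!is_finite_vector(x)) abort("IMF contains non-finite values")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  amp <- Mod(z)
  ph <- phase_unwrap(Arg(z))
  w <- numeric(n)
  w[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  w[1] <- ph[2] - ph[1]
  w[n] <- ph[n] - ph[n - 1]
  w <- w / (2 * pi)
  valid <- w >= 0
  w[!valid] <- 0
  w[w > 0.5] <- 0.5
  structure(list(amplitude = amp, phase = ph, inst_freq = w,
                 freq_valid = valid),
            class = "analytic_imf")
}

#' @export
print.analytic_imf <- function(x, ...) {
  cat(sprintf("<analytic_imf> N = %d, mean amplitude %.3g, median freq %.3g cyc/sample\n",
              length(x$amplitude), mean(x$amplitude), median(x$inst_freq)))
  invisible(x)
}

#' Hilbert amplitude spectrum H(w, n)
#'
#' Bins the instantaneous frequency of each IMF at each timepoint into
#' `n_bins` uniform bins over (0, 0.5] cycles/sample and accumulates the
#' corresponding instantaneous amplitudes, so column `n` holds the summed
#' amplitude of all IMFs whose frequency falls in each bin at time `n`.
#' Timepoints with invalid (clipped-negative) or exactly-zero frequency are
#' excluded from binning.
#'
#' @param analytic_imfs A list of [analytic_signal()] results (or a single
#'   one), all of the same length.
#' @param n_bins Number of frequency bins (>= 2, default 64).
#' @param trim Fraction of timepoints dropped at each end of the series
#'   (default 0) to suppress Hilbert end effects; the spectrum then has
#'   fewer columns.
#' @return Object of class `hilbert_spectrum`: list with `H` (n_bins x
#'   n_time matrix), `bin_edges` (length n_bins + 1 spanning 0 to 0.5), and
#'   `time_index` (retained original timepoints).
#' @export
hilbert_spectrum <- function(analytic_imfs, n_bins = 64L, trim = 0) {
  if (inherits(analytic_imfs, "analytic_imf")) analytic_imfs <- list(analytic_imfs)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be >= 2")
  check_scalar_number(trim, "trim", 0, 0.4)
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  if (!length(analytic_imfs)) {
    warn("no IMFs: Hilbert spectrum is all-zero")
    return(structure(list(H = matrix(0, n_bins, 0L), bin_edges = edges,
                          time_index = integer()),
                     class = "hilbert_spectrum"))
  }
  lens <- vapply(analytic_imfs, function(a) length(a$amplitude), integer(1))
  if (length(unique(lens)) != 1L) abort("IMFs have differing lengths")
  n <- lens[1]
  drop <- floor(trim * n)
  keep <- seq.int(drop + 1L, n - drop)
  H <- matrix(0, n_bins, length(keep))
  for (a in analytic_imfs) {
    w <- a$inst_freq[keep]
    amp <- a$amplitude[keep]
    ok <- a$freq_valid[keep] & w > 0
    if (!any(ok)) next
    bin <- pmin(ceiling(w[ok] * 2 * n_bins), n_bins)
    lin <- bin + (which(ok) - 1L) * n_bins
    acc <- rowsum(amp[ok], group = lin)
    at <- as.integer(rownames(acc))
    H[at] <- H[at] + acc[, 1]
  }
  structure(list(H = H, bin_edges = edges, time_index = keep),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d bins x %d timepoints, total amplitude %.4g\n",
              nrow(x$H), ncol(x$H), sum(x$H)))
  invisible(x)
}

as_spectrum <- function(H) {
  if (inherits(H, "hilbert_spectrum")) return(H)
  H <- as.matrix(H)
  structure(list(H = H, bin_edges = seq(0, 0.5, length.out = nrow(H) + 1L),
                 time_index = seq_len(ncol(H))),
            class = "hilbert_spectrum")
}

#' Marginal (time-summed) and average Hilbert spectra
#'
#' The marginal spectrum is `h(w) = sum_n H(w, n)` and the average boundary
#' spectrum `B(w) = h(w) / N`, with `N` the number of (retained) timepoints.
#'
#' @param spectrum A [hilbert_spectrum()] or a plain bins x time matrix.
#' @return Object of class `marginal_spectrum`: list with `h`, `B`,
#'   `bin_edges`, `n_time`.
#' @export
marginal_spectra <- function(spectrum) {
  sp <- as_spectrum(spectrum)
  n <- ncol(sp$H)
  h <- rowSums(sp$H)
  structure(list(h = h, B = if (n > 0) h / n else h, bin_edges = sp$bin_edges,
                 n_time = n),
            class = "marginal_spectrum")
}

#' Degree of stationarity DS(w)
#'
#' For each frequency bin, `DS(w) = mean_n (1 - H(w, n) / B(w))^2`: the mean
#' squared relative deviation of the Hilbert spectrum from its time average.
#' A spectrum constant over time in a bin gives DS = 0 there; any temporal
#' variation gives DS > 0. Bins with `B(w) = 0` carry no spectral content
#' and are excluded (not zero-filled). The per-voxel scalar is the
#' marginal-spectrum-weighted mean over valid bins,
#' `sum(h(w) DS(w)) / sum(h(w))`, which weights DS where the signal has
#' energy.
#'
#' @param spectrum A [hilbert_spectrum()] or plain bins x time matrix.
#' @param marginal Optional precomputed [marginal_spectra()] of `spectrum`.
#' @return Object of class `ds_profile`: list with `by_freq` (tibble of
#'   `bin`, `freq_lo`, `freq_hi`, `h`, `B`, `ds`, `valid`), `ds_scalar`,
#'   `n_valid_bins`, `n_time`.
#' @export
degree_of_stationarity <- function(spectrum, marginal = NULL) {
  sp <- as_spectrum(spectrum)
  if (any(sp$H < 0)) abort("Hilbert spectrum has negative amplitudes")
  marg <- marginal %||% marginal_spectra(sp)
  valid <- marg$B > 0
  if (!any(valid)) abort("no spectral content: every frequency bin is empty")
  n_bins <- nrow(sp$H)
  ds <- rep(NA_real_, n_bins)
  dev <- (1 - sp$H[valid, , drop = FALSE] / marg$B[valid])^2
  ds[valid] <- rowMeans(dev)
  ds_scalar <- sum(marg$h[valid] * ds[valid]) / sum(marg$h[valid])
  by_freq <- tibble(
    bin = seq_len(n_bins),
    freq_lo = sp$bin_edges[-(n_bins + 1L)],
    freq_hi = sp$bin_edges[-1L],
    h = marg$h, B = marg$B, ds = ds, valid = valid
  )
  structure(list(by_freq = by_freq, ds_scalar = ds_scalar,
                 n_valid_bins = sum(valid), n_time = ncol(sp$H)),
            class = "ds_profile")
}

#' @export
print.ds_profile <- function(x, ...) {
  cat(sprintf("<ds_profile> DS = %.4g over %d valid bins (%d timepoints)\n",
              x$ds_scalar, x$n_valid_bins, x$n_time))
  invisible(x)
}

#' @rdname degree_of_stationarity
#' @param x A `ds_profile`.
#' @param ... Unused.
#' @method tidy ds_profile
#' @export
tidy.ds_profile <- function(x, ...) x$by_freq

#' @rdname degree_of_stationarity
#' @param x A `ds_profile`.
#' @method glance ds_profile
#' @export
glance.ds_profile <- function(x, ...) {
  tibble(ds_scalar = x$ds_scalar, n_valid_bins = x$n_valid_bins,
         n_time = x$n_time)
}

#' HHT parameter bundle
#'
#' @param n_bins Frequency bins over (0, 0.5] cycles/sample (default 64).
#' @param trim Fraction of timepoints trimmed from each end before the DS
#'   statistic (default 0.05), suppressing Hilbert end effects.
#' @param sd_thresh,max_sift,max_imf Sifting controls, see [emd()].
#' @return Named list of parameters.
#' @export
hht_params <- function(n_bins = 64L, trim = 0.05, sd_thresh = 0.2,
                       max_sift = 100L, max_imf = 12L) {
  list(n_bins = as.integer(n_bins), trim = trim, sd_thresh = sd_thresh,
       max_sift = as.integer(max_sift), max_imf = as.integer(max_imf))
}

#' Degree of stationarity of one series
#'
#' Full chain: [emd()], [analytic_signal()] per IMF, [hilbert_spectrum()]
#' with edge trimming, [marginal_spectra()], [degree_of_stationarity()].
#' Fully deterministic.
#'
#' @param x Numeric series (length >= 64, non-constant).
#' @param params An [hht_params()] list.
#' @return A `ds_profile`.
#' @export
ds_for_voxel <- function(x, params = hht_params()) {
  dec <- emd(x, sd_thresh = params$sd_thresh, max_sift = params$max_sift,
             max_imf = params$max_imf)
  if (!length(dec$imfs)) abort("no oscillatory component: EMD produced no IMFs")
  an <- lapply(dec$imfs, analytic_signal)
  sp <- hilbert_spectrum(an, n_bins = params$n_bins, trim = params$trim)
  degree_of_stationarity(sp)
}

#' Voxel-wise DS map
#'
#' Applies [ds_for_voxel()] to every row of an [fmri_series()]. Degenerate
#' voxels (constant series, no spectral content) are recorded as `NA` with a
#' message; more than 50% degenerate aborts.
#'
#' @param series An [fmri_series()].
#' @param params An [hht_params()] list.
#' @return Tibble with `voxel`, `i`, `j`, `k`, `ds`, `n_valid_bins`.
#' @export
ds_map <- function(series, params = hht_params()) {
  if (!inherits(series, "fmri_series")) abort("`series` must be an fmri_series")
  v <- nrow(series$values)
  ds <- rep(NA_real_, v)
  nvb <- rep(NA_integer_, v)
  for (r in seq_len(v)) {
    prof <- tryCatch(ds_for_voxel(series$values[r, ], params),
                     error = function(e) NULL)
    if (!is.null(prof)) {
      ds[r] <- prof$ds_scalar
      nvb[r] <- prof$n_valid_bins
    }
  }
  n_bad <- sum(is.na(ds))
  if (n_bad > v / 2) {
    abort(sprintf("DS map aborted: %d of %d voxels degenerate", n_bad, v))
  }
  if (n_bad > 0) inform(sprintf("%d of %d voxels degenerate (DS = NA)", n_bad, v))
  dplyr::bind_cols(voxel_coords(series$geometry),
                   tibble(ds = ds, n_valid_bins = nvb))
}
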
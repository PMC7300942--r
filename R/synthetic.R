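# Synthetic multi-subject, multi-session datasets with known
# stationarity/linearity classes and planted variance components.

process_kinds <- function() {
  c("ar_linear", "am_fm_nonstationary", "nonlinear_map", "nonlinear_nonstationary")
}

#' Specification of a voxel signal-generating process
#'
#' Four classes emulate the signal families the DS/DN analysis
#' distinguishes: `ar_linear` (stationary linear Gaussian AR),
#' `am_fm_nonstationary` (amplitude- and frequency-modulated tone),
#' `nonlinear_map` (dynamically non-linear series; default a bilinear AR
#' process with multiplicative noise coupling, with a logistic map or a
#' static cubic distortion as alternatives), and `nonlinear_nonstationary`
#' (amplitude-modulated bilinear process). The bilinear default is chosen
#' because its non-linearity is dynamical: it survives band-pass filtering
#' and lies outside the null class of amplitude-adjusted surrogates,
#' whereas a static monotone distortion is by construction part of that
#' null. Each kind designates one scalar parameter (AR coefficient,
#' modulation depth, non-linear coupling strength) that carries the
#' subject/session perturbation.
#'
#' @param kind One of the four process kinds.
#' @param snr Signal-to-noise power ratio of the additive Gaussian noise
#'   that is band-limited together with the signal (default 2).
#' @param params Kind-specific overrides: `ar` (coefficients, stable),
#'   `am_freq`, `am_depth`, `f0`, `f1` (Hz), `map` ("bilinear", "logistic"
#'   or "cubic"), `strength` (non-linear coupling / distortion strength).
#' @return Object of class `process_spec`.
#' @export
process_spec <- function(kind = process_kinds(), snr = 2, params = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    ar_linear = list(ar = c(0.5, 0.2)),
    am_fm_nonstationary = list(am_freq = 0.01, am_depth = 1.0,
                               f0 = 0.03, f1 = 0.06),
    nonlinear_map = list(map = "bilinear", ar = c(0.5, 0.2), strength = 0.8),
    nonlinear_nonstationary = list(map = "bilinear", ar = c(0.5, 0.2),
                                   strength = 0.8, am_freq = 0.01,
                                   am_depth = 1.0))
  p <- utils::modifyList(defaults, params)
  if (!is.null(p$ar)) {
    if (any(Mod(polyroot(c(1, -p$ar))) <= 1)) {
      abort("unstable AR coefficients: roots must lie outside the unit circle")
    }
  }
  check_scalar_number(snr, "snr", lower = 1e-6)
  structure(list(kind = kind, snr = snr, params = p), class = "process_spec")
}

#' @export
print.process_spec <- function(x, ...) {
  cat(sprintf("<process_spec> %s, SNR %.3g\n", x$kind, x$snr))
  invisible(x)
}

stationary_kind <- function(kind) kind %in% c("ar_linear", "nonlinear_map")
linear_kind <- function(kind) kind %in% c("ar_linear", "am_fm_nonstationary")

# Clamp an AR(2)-style coefficient vector to stay well inside stability
clamp_ar <- function(ar, adjust) {
  ar[1] <- ar[1] * adjust
  total <- sum(abs(ar))
  if (total > 0.95) ar <- ar * 0.95 / total
  ar
}

#' Generate one synthetic voxel time series
#'
#' Deterministic given `seed`. The raw process is built per the
#' [process_spec()], additive Gaussian noise is mixed in at the spec's SNR,
#' the sum is band-pass filtered (static distortions are applied after
#' filtering, as a memoryless output nonlinearity), and the result is
#' standardised to unit variance.
#'
#' @param spec A [process_spec()].
#' @param n Length (>= 64).
#' @param tr Sampling interval in seconds.
#' @param seed Integer seed.
#' @param band Band edges in Hz (`NULL` to skip filtering, e.g. for
#'   spectral checks on the raw process).
#' @param param_adjust Multiplier on the kind's designated scalar parameter
#'   (modulation depth, distortion strength, leading AR coefficient); used
#'   by [generate_dataset()] to plant subject/session structure.
#' @return Numeric series of length `n`, unit variance.
#' @export
gen_signal <- function(spec, n, tr, seed = 1L, band = c(0.009, 0.08),
                       param_adjust = 1) {
  if (!inherits(spec, "process_spec")) abort("`spec` must be a process_spec")
  n <- as.integer(n)
  if (n < 64L) abort("`n` must be >= 64")
  check_scalar_number(tr, "tr", lower = 1e-6)
  check_scalar_number(param_adjust, "param_adjust", lower = 0)
  p <- spec$params
  with_seed(seed, {
    raw <- switch(spec$kind,
      ar_linear = {
        as.numeric(arima.sim(list(ar = clamp_ar(p$ar, param_adjust)), n))
      },
      am_fm_nonstationary = am_fm_tone(p, n, tr, param_adjust),
      nonlinear_map = nonlinear_core(p, n, param_adjust),
      nonlinear_nonstationary = nonlinear_core(p, n, param_adjust))
    raw <- raw / sd(raw)
    y <- raw + rnorm(n, sd = sqrt(1 / spec$snr))
    if (!is.null(band)) y <- bp_single(y, tr, band[1], band[2])
    if (identical(p$map, "cubic")) {
      # static memoryless output distortion, applied after filtering
      y <- y / sd(y)
      y <- y + (p$strength * param_adjust) * y^3
    }
    if (spec$kind == "nonlinear_nonstationary") {
      t <- (0:(n - 1)) * tr
      depth <- min(p$am_depth * param_adjust, 1.2)
      y <- y * (1 + depth * cos(2 * pi * p$am_freq * t + runif(1, 0, 2 * pi)))
    }
    y <- y - mean(y)
    y / sd(y)
  })
}

# dynamically non-linear core series (before noise/filtering)
nonlinear_core <- function(p, n, adjust) {
  map <- p$map %||% "bilinear"
  if (identical(map, "logistic")) return(logistic_series(n))
  if (identical(map, "cubic")) {
    return(as.numeric(arima.sim(list(ar = p$ar), n)))  # distorted later
  }
  bilinear_series(p$ar, p$strength * adjust, n)
}

# bilinear AR: x_t = a1 x_{t-1} + a2 x_{t-2} + b x_{t-1} e_{t-1} + e_t.
# Second-moment stationarity needs roughly sum(ar^2) + b^2 < 1; b is
# clamped to keep the process from degenerating.
bilinear_series <- function(ar, b, n, burn = 100L) {
  a1 <- ar[1]
  a2 <- if (length(ar) > 1) ar[2] else 0
  b <- min(b, sqrt(max(0.95 - a1^2 - a2^2, 0.01)))
  total <- n + burn
  e <- rnorm(total)
  x <- numeric(total)
  for (t in 3:total) {
    x[t] <- a1 * x[t - 1] + a2 * x[t - 2] + b * x[t - 1] * e[t - 1] + e[t]
  }
  x[(burn + 1L):total]
}

am_fm_tone <- function(p, n, tr, adjust) {
  t <- (0:(n - 1)) * tr
  span <- n * tr
  depth <- min(p$am_depth * adjust, 1.2)
  phi <- runif(1, 0, 2 * pi)
  psi <- runif(1, 0, 2 * pi)
  env <- 1 + depth * cos(2 * pi * p$am_freq * t + phi)
  phase <- 2 * pi * (p$f0 * t + (p$f1 - p$f0) / (2 * span) * t^2) + psi
  env * cos(phase)
}

logistic_series <- function(n, burn = 100L) {
  v <- numeric(n + burn)
  v[1] <- runif(1, 0.1, 0.9)
  for (i in seq_len(n + burn - 1L)) v[i + 1L] <- 4 * v[i] * (1 - v[i])
  v[(burn + 1L):(n + burn)]
}

#' Default seven-network block layout
#'
#' Splits the first grid axis into seven slabs, one per network, restricted
#' to the middle slices of the third axis so that (as for a gray-matter
#' mask) a realistic fraction of the volume is background. Network process
#' classes: DAN and FPN stationary-linear AR; VN and SMN
#' amplitude/frequency modulated (non-stationary); LIMB and DMN bilinear
#' (non-linear); VAN both.
#'
#' @param dims Grid dimensions (first axis must be >= 7).
#' @param snr Signal-to-noise ratio handed to every [process_spec()].
#' @return Tibble with `network`, `kind`, and block bounds `x_lo`, `x_hi`,
#'   `y_lo`, `y_hi`, `z_lo`, `z_hi`.
#' @export
default_network_layout <- function(dims = c(8, 8, 4), snr = 2) {
  if (dims[1] < 7L) abort("first grid axis must be >= 7 for the default layout")
  kinds <- c(VN = "am_fm_nonstationary", SMN = "am_fm_nonstationary",
             DAN = "ar_linear", VAN = "nonlinear_nonstationary",
             LIMB = "nonlinear_map", FPN = "ar_linear",
             DMN = "nonlinear_map")
  z_lo <- max(1L, floor(dims[3] / 4) + 1L)
  z_hi <- min(as.integer(dims[3]), z_lo + max(1L, ceiling(dims[3] / 2)) - 1L)
  tibble(network = network_names(), kind = unname(kinds[network_names()]),
         x_lo = 1:7, x_hi = 1:7, y_lo = 1L, y_hi = as.integer(dims[2]),
         z_lo = z_lo, z_hi = z_hi)
}

#' Specification of a synthetic multi-scan dataset
#'
#' Emulates the structure of a test-retest resting-state study: multiple
#' subjects with repeated sessions, band-limited voxel series on a small
#' grid with a seven-network block atlas, and a per-voxel scalar process
#' parameter perturbed with between-subject variance `sigma_b2` and
#' within-subject (session) variance `sigma_w2`, so the planted parameter
#' has population ICC `sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' @param grid_dims Grid dimensions (default 8 x 8 x 4).
#' @param n_subjects,k_sessions Panel shape (defaults 5 x 3).
#' @param n_time Timepoints per scan (default 256).
#' @param tr Sampling interval in seconds (default 2).
#' @param sigma_b2,sigma_w2 Variance components of the parameter
#'   perturbation (defaults 0.6 / 0.4, planted ICC 0.6).
#' @param snr Signal-to-noise ratio (default 2).
#' @param band Band-pass edges in Hz (default 0.009-0.08).
#' @param network_layout A [default_network_layout()]-shaped tibble.
#' @param seed Integer seed; the dataset is byte-reproducible given it.
#' @return Object of class `dataset_spec`.
#' @export
dataset_spec <- function(grid_dims = c(8, 8, 4), n_subjects = 5L,
                         k_sessions = 3L, n_time = 256L, tr = 2,
                         sigma_b2 = 0.6, sigma_w2 = 0.4, snr = 2,
                         band = c(0.009, 0.08),
                         network_layout = default_network_layout(grid_dims, snr),
                         seed = 1L) {
  if (sigma_b2 < 0 || sigma_w2 < 0) abort("variance components must be >= 0")
  if (!all(network_layout$network %in% network_names())) {
    abort("layout labels outside the 7-network vocabulary")
  }
  if (!all(network_layout$kind %in% process_kinds())) {
    abort("unknown process kind in layout")
  }
  if (any(network_layout$x_hi > grid_dims[1] | network_layout$y_hi > grid_dims[2] |
          network_layout$z_hi > grid_dims[3])) {
    abort("layout blocks do not fit the grid")
  }
  structure(list(grid_dims = as.integer(grid_dims),
                 n_subjects = as.integer(n_subjects),
                 k_sessions = as.integer(k_sessions),
                 n_time = as.integer(n_time), tr = tr,
                 sigma_b2 = sigma_b2, sigma_w2 = sigma_w2, snr = snr,
                 band = band, network_layout = network_layout,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

layout_labels <- function(spec) {
  lab <- array(0L, spec$grid_dims)
  lay <- spec$network_layout
  for (r in seq_len(nrow(lay))) {
    code <- match(lay$network[r], network_names())
    block <- lab[lay$x_lo[r]:lay$x_hi[r], lay$y_lo[r]:lay$y_hi[r],
                 lay$z_lo[r]:lay$z_hi[r]]
    if (any(block != 0L)) abort("overlapping layout blocks")
    lab[lay$x_lo[r]:lay$x_hi[r], lay$y_lo[r]:lay$y_hi[r],
        lay$z_lo[r]:lay$z_hi[r]] <- code
  }
  lab
}

#' Generate a synthetic dataset
#'
#' Builds every scan (subject x session) as an [fmri_series()] on a common
#' mask and block atlas, together with a per-voxel truth table (network,
#' process kind, stationarity/linearity flags) and the planted per-scan
#' parameter draws. Fully reproducible given the spec's seed. When `dir`
#' is given, scans, mask, atlas and truth tables are also written to disk
#' (NIfTI + TSV).
#'
#' @param spec A [dataset_spec()].
#' @param dir Optional output directory.
#' @param signals Set `FALSE` to skip signal synthesis and return only the
#'   mask, atlas, truth table and parameter draws (cheap planning mode,
#'   e.g. for variance-component checks).
#' @return Object of class `dsdn_dataset`: list with `spec`, `geometry`,
#'   `atlas` (a `network_atlas`), `scans` (tibble `subject`, `session`,
#'   `series` list-column, and `path` when written), `truth` (per-voxel
#'   tibble), `draws` (per voxel x subject x session parameter draws).
#' @export
generate_dataset <- function(spec, dir = NULL, signals = TRUE) {
  if (!inherits(spec, "dataset_spec")) abort("`spec` must be a dataset_spec")
  lab <- layout_labels(spec)
  mask_idx <- which(lab != 0L)
  geom <- grid_geometry(spec$grid_dims, voxel_size = c(4, 4, 4),
                        mask_idx = mask_idx)
  atlas <- structure(list(labels = lab, label_map = yeo7_label_map(),
                          affine = geom$affine),
                     class = "network_atlas")
  nets <- atlas_networks(atlas, geom)
  lay <- spec$network_layout
  kind_of_net <- setNames(lay$kind, lay$network)
  truth <- dplyr::mutate(
    nets,
    kind = unname(kind_of_net[as.character(.data$network)]),
    stationary = stationary_kind(.data$kind),
    linear = linear_kind(.data$kind))
  truth <- dplyr::bind_cols(voxel_coords(geom)[, c("i", "j", "k")], truth) |>
    dplyr::relocate("voxel")
  v <- length(mask_idx)
  # planted perturbation: b (subject x voxel) + w (scan x voxel), drawn in a
  # fixed order under the dataset seed
  draws <- with_seed(spec$seed, {
    b <- matrix(rnorm(spec$n_subjects * v, 0, sqrt(spec$sigma_b2)),
                spec$n_subjects, v)
    w <- array(rnorm(spec$n_subjects * spec$k_sessions * v, 0,
                     sqrt(spec$sigma_w2)),
               c(spec$n_subjects, spec$k_sessions, v))
    tidyr::crossing(subject = seq_len(spec$n_subjects),
                    session = seq_len(spec$k_sessions),
                    voxel = seq_len(v)) |>
      dplyr::mutate(param_draw = b[cbind(.data$subject, .data$voxel)] +
                      w[cbind(.data$subject, .data$session, .data$voxel)],
                    param_adjust = exp(0.25 * .data$param_draw))
  })
  specs_by_kind <- lapply(setNames(nm = unique(truth$kind)), function(kd) {
    process_spec(kd, snr = spec$snr)
  })
  scans <- tidyr::crossing(subject = seq_len(spec$n_subjects),
                           session = seq_len(spec$k_sessions))
  if (!signals) {
    return(structure(list(spec = spec, geometry = geom, atlas = atlas,
                          scans = scans, truth = truth, draws = draws),
                     class = "dsdn_dataset"))
  }
  draw_adj <- matrix(draws$param_adjust[order(draws$subject, draws$session, draws$voxel)],
                     nrow = v)
  # columns of draw_adj follow crossing order: session fastest within subject
  scan_col <- function(i, s) (i - 1L) * spec$k_sessions + s
  series_list <- vector("list", nrow(scans))
  for (rr in seq_len(nrow(scans))) {
    i <- scans$subject[rr]
    s <- scans$session[rr]
    vals <- matrix(0, v, spec$n_time)
    adj <- draw_adj[, scan_col(i, s)]
    for (vv in seq_len(v)) {
      sd_seed <- derive_seed(spec$seed, (i * 100 + s) * 100000 + vv)
      vals[vv, ] <- gen_signal(specs_by_kind[[truth$kind[vv]]], spec$n_time,
                               spec$tr, seed = sd_seed, band = spec$band,
                               param_adjust = adj[vv])
    }
    series_list[[rr]] <- fmri_series(vals, geom, spec$tr)
  }
  scans$series <- series_list
  out <- structure(list(spec = spec, geometry = geom, atlas = atlas,
                        scans = scans, truth = truth, draws = draws),
                   class = "dsdn_dataset")
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' @export
print.dsdn_dataset <- function(x, ...) {
  cat(sprintf("<dsdn_dataset> %d subjects x %d sessions, %d voxels x %d timepoints\n",
              x$spec$n_subjects, x$spec$k_sessions,
              length(x$geometry$mask_idx), x$spec$n_time))
  invisible(x)
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- dataset$geometry
  mask <- array(0, geom$dims)
  mask[geom$mask_idx] <- 1
  mask_img <- RNifti::asNifti(mask)
  RNifti::pixdim(mask_img) <- geom$voxel_size
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii.gz"))
  atlas_img <- RNifti::asNifti(dataset$atlas$labels + 0)
  RNifti::pixdim(atlas_img) <- geom$voxel_size
  RNifti::writeNifti(atlas_img, file.path(dir, "atlas.nii.gz"))
  paths <- character(nrow(dataset$scans))
  for (rr in seq_len(nrow(dataset$scans))) {
    sc <- dataset$scans[rr, ]
    arr <- array(0, c(geom$dims, dataset$spec$n_time))
    flat <- matrix(arr, prod(geom$dims), dataset$spec$n_time)
    flat[geom$mask_idx, ] <- sc$series[[1]]$values
    arr <- array(flat, c(geom$dims, dataset$spec$n_time))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(geom$voxel_size, dataset$spec$tr)
    paths[rr] <- file.path(dir, sprintf("sub-%02d_ses-%02d.nii.gz",
                                        sc$subject, sc$session))
    RNifti::writeNifti(img, paths[rr])
  }
  dataset$scans$path <- paths
  write_tsv_plain(dataset$truth, file.path(dir, "truth.tsv"))
  write_tsv_plain(dataset$draws, file.path(dir, "draws.tsv"))
  invisible(dataset)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df)) if (is.factor(df[[cl]])) df[[cl]] <- as.character(df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
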
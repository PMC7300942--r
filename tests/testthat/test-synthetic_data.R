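# Synthetic signal generator and dataset builder.

test_that("gen_signal is deterministic, unit variance, and rejects bad specs", {
  sp <- process_spec("ar_linear")
  x1 <- gen_signal(sp, 256, 2, seed = 3)
  x2 <- gen_signal(sp, 256, 2, seed = 3)
  expect_identical(x1, x2)
  expect_false(identical(x1, gen_signal(sp, 256, 2, seed = 4)))
  expect_equal(sd(x1), 1, tolerance = 1e-12)
  for (kd in c("am_fm_nonstationary", "nonlinear_map", "nonlinear_nonstationary")) {
    x <- gen_signal(process_spec(kd), 128, 2, seed = 5)
    expect_length(x, 128)
    expect_true(all(is.finite(x)))
  }
  expect_error(process_spec("ar_linear", params = list(ar = c(1.2))), "unstable")
  expect_error(gen_signal(sp, 32, 2), ">= 64")
})

test_that("the AR process spectrum matches the transfer-function oracle", {
  sp <- process_spec("ar_linear", snr = 1e8)  # essentially noise-free
  x <- gen_signal(sp, 4096, 1, seed = 21, band = NULL)
  pg <- spec.pgram(x, taper = 0, plot = FALSE, detrend = FALSE)
  ar <- sp$params$ar
  theo <- vapply(pg$freq, function(f) {
    1 / Mod(1 - ar[1] * exp(-2i * pi * f) - ar[2] * exp(-4i * pi * f))^2
  }, numeric(1))
  # average raw periodogram and transfer function over 16 frequency bands
  band <- cut(pg$freq, 16)
  got <- tapply(pg$spec, band, mean)
  want <- tapply(theo, band, mean)
  got <- got / mean(got)
  want <- want / mean(want)
  expect_lt(sqrt(mean((got - want)^2)) / sqrt(mean(want^2)), 0.1)
})

test_that("the modulated class has a more variable slow envelope than the AR class", {
  # running-mean smoothing isolates the slow (deliberate) amplitude
  # modulation from the fast sample-scale envelope fluctuation any
  # narrowband Gaussian process shows
  slow_cv2 <- function(x) {
    a <- analytic_signal(x)$amplitude
    # 26 s window: a quarter of the planted 100 s modulation period, well
    # above the ~14 s coherence time of the band-limited noise envelope
    sm <- stats::filter(a, rep(1 / 13, 13), sides = 2)
    sm <- sm[!is.na(sm)]
    sm <- sm[13:(length(sm) - 12)]
    var(sm) / mean(sm)^2
  }
  hits <- 0
  for (seed in 1:100) {
    am <- gen_signal(process_spec("am_fm_nonstationary"), 256, 2, seed = 300 + seed)
    ar <- gen_signal(process_spec("ar_linear"), 256, 2, seed = 700 + seed)
    hits <- hits + (slow_cv2(am) > slow_cv2(ar))
  }
  expect_gte(hits, 95)
})

test_that("generated datasets honour the layout plan and are reproducible", {
  spec <- dataset_spec(grid_dims = c(8, 8, 4), n_subjects = 2, k_sessions = 2,
                       n_time = 64, seed = 11)
  d <- generate_dataset(spec)
  counts <- table(d$truth$network)
  lay <- spec$network_layout
  planned <- (lay$x_hi - lay$x_lo + 1) * (lay$y_hi - lay$y_lo + 1) *
    (lay$z_hi - lay$z_lo + 1)
  expect_equal(as.integer(counts[lay$network]), planned)
  expect_equal(nrow(d$scans), 4L)
  expect_equal(dim(d$scans$series[[1]]$values), c(sum(planned), 64L))
  d2 <- generate_dataset(spec)
  expect_identical(d$scans$series[[2]]$values, d2$scans$series[[2]]$values)
  expect_identical(d$draws, d2$draws)
  # overlapping blocks are rejected
  bad <- spec
  bad$network_layout$x_lo[2] <- 1L
  expect_error(generate_dataset(bad), "overlap")
})

test_that("dataset files round-trip through NIfTI and the atlas matches the plan", {
  spec <- dataset_spec(grid_dims = c(8, 4, 2), n_subjects = 1, k_sessions = 1,
                       n_time = 64, seed = 13)
  dir <- tempfile("dsdn_data_")
  d <- generate_dataset(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "mask.nii.gz")))
  ser <- read_volume_series(file.path(dir, "sub-01_ses-01.nii.gz"),
                            file.path(dir, "mask.nii.gz"))
  expect_equal(ser$values, d$scans$series[[1]]$values, tolerance = 1e-6)
  atlas <- load_network_atlas(file.path(dir, "atlas.nii.gz"))
  nets <- atlas_networks(atlas, d$geometry)
  expect_equal(as.character(nets$network), as.character(d$truth$network))
})

test_that("the planted parameter perturbation carries the designed ICC", {
  iccs <- numeric(100)
  for (rep_ in 1:100) {
    spec <- dataset_spec(grid_dims = c(7, 1, 1), n_subjects = 10, k_sessions = 5,
                         n_time = 64, sigma_b2 = 0.6, sigma_w2 = 0.4,
                         seed = 5000 + rep_)
    d <- generate_dataset(spec, signals = FALSE)
    # parameter-level ICC, averaged over voxels
    iccs[rep_] <- mean(vapply(unique(d$draws$voxel), function(vv) {
      dd <- d$draws[d$draws$voxel == vv, ]
      icc_consistency(matrix(dd$param_draw[order(dd$session, dd$subject)],
                             spec$n_subjects, spec$k_sessions))$icc
    }, numeric(1)))
  }
  expect_lt(abs(mean(iccs) - 0.6), 0.05)
})
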
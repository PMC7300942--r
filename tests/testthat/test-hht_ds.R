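# EMD, Hilbert spectral analysis, and the degree of stationarity.

test_that("EMD reconstructs exactly and separates well-spaced tones", {
  for (seed in 1:10) {
    x <- random_band_signal(512, seed)
    dec <- emd(x)
    recon <- Reduce(`+`, dec$imfs, dec$residual)
    expect_lt(sqrt(sum((x - recon)^2)) / sqrt(sum(x^2)), 1e-8)
    expect_true(all(vapply(dec$imfs, dsdn:::imf_property_ok, logical(1))))
  }
  n <- 1024
  fast <- cos(2 * pi * 0.1 * (0:(n - 1)))
  slow <- 0.8 * cos(2 * pi * 0.01 * (0:(n - 1)))
  dec <- emd(fast + slow)
  expect_gte(length(dec$imfs), 2)
  expect_gt(abs(cor(dec$imfs[[1]], fast)), 0.95)
  expect_gt(abs(cor(dec$imfs[[2]], slow)), 0.95)
})

test_that("EMD handles monotone and degenerate inputs per contract", {
  ramp <- seq(0, 1, length.out = 128)
  dec <- emd(ramp)
  expect_length(dec$imfs, 0)
  expect_equal(dec$residual, ramp)
  expect_error(emd(rep(1, 128)), "degenerate")
  expect_error(emd(rnorm(32)), "short")
})

test_that("analytic signal recovers amplitude and frequency of known components", {
  n <- 512
  tone <- cos(2 * pi * 0.1 * (0:(n - 1)))
  a <- analytic_signal(tone)
  core <- 50:462
  expect_true(all(abs(a$amplitude[core] - 1) < 0.02))
  expect_true(all(abs(a$inst_freq[core] - 0.1) < 0.005))
  env <- 1 + 0.5 * cos(2 * pi * 0.01 * (0:(n - 1)))
  am <- env * cos(2 * pi * 0.1 * (0:(n - 1)))
  aa <- analytic_signal(am)
  expect_gt(cor(aa$amplitude[core], env[core]), 0.95)
  z <- analytic_signal(rep(0, 64))
  expect_equal(z$amplitude, rep(0, 64))
})

test_that("Hilbert spectrum bins tones correctly and conserves amplitude", {
  n <- 640  # whole number of cycles: the discrete analytic tone is exact
  tone <- cos(2 * pi * 0.1 * (0:(n - 1)))
  sp <- hilbert_spectrum(analytic_signal(tone), n_bins = 64, trim = 0.05)
  # every column has exactly one occupied bin: the one containing 0.1
  occupied <- apply(sp$H > 0, 2, which)
  expect_true(all(lengths(occupied) == 1))
  expect_true(all(unlist(occupied) == ceiling(0.1 * 2 * 64)))
  # two tones in different bins: per-column totals are the amplitude sum
  two <- lapply(list(tone, 0.7 * cos(2 * pi * 0.2 * (0:(n - 1)))),
                analytic_signal)
  sp2 <- hilbert_spectrum(two, n_bins = 64, trim = 0.05)
  amp_total <- colSums(do.call(rbind, lapply(two, function(a) a$amplitude)))
  expect_equal(colSums(sp2$H), amp_total[sp2$time_index], tolerance = 1e-10)
  # a linear chirp sweeps upward: the occupied bin is non-decreasing up to
  # discretisation ripple of the phase-derivative estimate
  inst <- 0.05 + (0.15 - 0.05) * (0:511) / 512
  chirp <- cos(2 * pi * cumsum(inst))
  spc <- hilbert_spectrum(analytic_signal(chirp), n_bins = 32, trim = 0.05)
  bins <- apply(spc$H > 0, 2, which.max)
  expect_gte(mean(diff(bins) >= 0), 0.99)
  expect_gte(bins[length(bins)] - bins[1], 5)
  expect_warning(hilbert_spectrum(list(), n_bins = 8), "no IMFs")
})

test_that("marginal spectra are row sums and time averages", {
  H <- matrix(c(1, 0, 1, 2), 2, 2)  # rows: [1,1], [0,2]
  m <- marginal_spectra(H)
  expect_equal(m$h, c(2, 2))
  expect_equal(m$B, c(1, 1))
  expect_equal(sum(m$h), sum(H))
  z <- marginal_spectra(matrix(0, 3, 4))
  expect_equal(z$h, rep(0, 3))
})

test_that("DS is zero iff the spectrum is constant over time, positive otherwise", {
  H0 <- rbind(rep(1, 8), rep(3, 8))
  prof <- degree_of_stationarity(H0)
  expect_equal(prof$by_freq$ds[prof$by_freq$valid], c(0, 0))
  expect_equal(prof$ds_scalar, 0)
  H1 <- matrix(c(2, 0, 2, 0), 1, 4)
  prof1 <- degree_of_stationarity(H1)
  expect_equal(prof1$by_freq$ds[1], 1)  # ((1-2)^2+1+(1-2)^2+1)/4
  for (seed in 1:20) {
    H <- matrix(abs(rnorm(40, 1)), 4, 10)
    p <- degree_of_stationarity(H)
    expect_true(all(p$by_freq$ds[p$by_freq$valid] >= 0))
    expect_gt(p$ds_scalar, 0)
  }
  expect_error(degree_of_stationarity(matrix(0, 2, 4)), "no spectral content")
})

test_that("a steady tone is more stationary than a modulated tone, deterministically", {
  n <- 1024
  wins <- 0
  for (seed in 1:20) {
    ph <- dsdn:::with_seed(seed, runif(2, 0, 2 * pi))
    tone <- cos(2 * pi * 0.1 * (0:(n - 1)) + ph[1])
    env <- 1 + 0.9 * cos(2 * pi * 0.005 * (0:(n - 1)) + ph[2])
    inst <- 0.08 + 0.04 * (0:(n - 1)) / n
    mod <- env * cos(2 * pi * cumsum(inst))
    mod <- mod * sd(tone) / sd(mod)
    wins <- wins + (ds_for_voxel(tone)$ds_scalar < ds_for_voxel(mod)$ds_scalar)
  }
  expect_equal(wins, 20)
  x <- random_band_signal(256, 7)
  expect_identical(ds_for_voxel(x), ds_for_voxel(x))
  # for a pure tone, marginal energy concentrates in at most 2 adjacent bins
  tone <- cos(2 * pi * 0.1 * (0:1023))
  prof <- ds_for_voxel(tone)
  hot <- which(prof$by_freq$h > 0.01 * sum(prof$by_freq$h))
  expect_lte(length(hot), 2)
  if (length(hot) == 2) expect_equal(diff(hot), 1)
})

test_that("ds_map is per-voxel, equivariant under row permutation, and flags degenerates", {
  vals <- rbind(t(sapply(1:5, function(s) gen_signal(process_spec("am_fm_nonstationary"), 128, 2, seed = s))),
                t(sapply(6:10, function(s) gen_signal(process_spec("ar_linear"), 128, 2, seed = s))))
  ser <- series_from_matrix(vals)
  m <- ds_map(ser)
  expect_equal(nrow(m), 10)
  expect_gt(median(m$ds[1:5]), median(m$ds[6:10]))
  perm <- c(3, 1, 2, 7, 10, 4, 6, 5, 9, 8)
  mp <- ds_map(series_from_matrix(vals[perm, ]))
  expect_equal(mp$ds, m$ds[perm])
  single <- ds_map(series_from_matrix(vals[1, , drop = FALSE]))
  expect_equal(nrow(single), 1)
  bad <- vals
  bad[1:6, ] <- 1
  expect_error(ds_map(series_from_matrix(bad)), "degenerate")
})
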
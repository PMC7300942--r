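# ICC reliability, two-sample tests, correlations, similarity analyses.

test_that("ICC matches hand-derived panels and the ANOVA oracle", {
  r1 <- icc_consistency(rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r1$bms, 8)
  expect_equal(r1$ems, 0)
  expect_equal(r1$icc, 1)
  r2 <- icc_consistency(rbind(c(1, 2), c(2, 1)))
  expect_equal(r2$bms, 0)
  expect_equal(r2$ems, 1)
  expect_equal(r2$icc, -1)
  for (seed in 1:100) {
    x <- dsdn:::with_seed(seed, matrix(rnorm(5 * 4), 5, 4))
    got <- icc_consistency(x)
    expect_equal(got$icc, icc_oracle(x), tolerance = 1e-10)
    expect_lte(got$icc, 1)
  }
  flat <- icc_consistency(matrix(2, 3, 3))
  expect_false(flat$defined)
  expect_true(is.na(flat$icc))
})

test_that("icc_map vectorises the panel computation and flags significance", {
  n <- 6
  k <- 4
  v <- 25
  panel <- tidyr::crossing(subject = 1:n, session = 1:k, voxel = 1:v)
  panel$value <- dsdn:::with_seed(8, {
    subj_eff <- matrix(rnorm(n * v), n, v)
    subj_eff[cbind(panel$subject, panel$voxel)] + rnorm(nrow(panel), sd = 0.5)
  })
  m <- icc_map(panel)
  expect_equal(nrow(m), v)
  for (vv in c(1, 13, 25)) {
    x <- matrix(panel$value[panel$voxel == vv][order(panel$session[panel$voxel == vv],
                                                     panel$subject[panel$voxel == vv])],
                n, k)
    expect_equal(m$icc[m$voxel == vv], icc_oracle(x), tolerance = 1e-10)
  }
  expect_equal(m$significant, m$p_value < 0.05)
  m_bh <- icc_map(panel, adjust = "BH")
  expect_equal(m_bh$significant, stats::p.adjust(m$p_value, "BH") < 0.05)
  expect_lte(sum(m_bh$significant), sum(m$significant))
  # identical sessions within subject, distinct subjects -> ICC 1 everywhere
  perfect <- tidyr::crossing(subject = 1:4, session = 1:3, voxel = 1:5)
  perfect$value <- perfect$subject * 1.5 + perfect$voxel
  expect_true(all(icc_map(perfect)$icc == 1))
  expect_error(icc_map(panel[-1, ]), "misaligned")
})

test_that("planted variance components are recovered and nulls sit near zero", {
  n <- 50
  k <- 10
  est_null <- est_icc <- numeric(200)
  for (rep_ in 1:200) {
    est_null[rep_] <- dsdn:::with_seed(rep_, {
      icc_consistency(matrix(rnorm(n * k), n, k))$icc
    })
    est_icc[rep_] <- dsdn:::with_seed(1000 + rep_, {
      b <- rnorm(n, 0, sqrt(0.6))
      icc_consistency(matrix(b + rnorm(n * k, 0, sqrt(0.4)), n, k))$icc
    })
  }
  expect_lt(abs(mean(est_null)), 0.05)
  expect_lt(abs(mean(est_icc) - 0.6), 0.05)
})

test_that("welch_t matches the direct formula and behaves symmetrically", {
  got <- welch_t(c(1, 2, 3), c(4, 5, 6))
  want <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  a <- dsdn:::with_seed(9, rnorm(10))
  b <- dsdn:::with_seed(10, rnorm(12, 1, 2))
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  expect_error(welch_t(c(1, 1), c(1, 1)), "degenerate")
})

test_that("pearson_r matches the covariance formula and hits the exact limits", {
  x <- dsdn:::with_seed(11, rnorm(30))
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 5)$r, -1)
  for (seed in 1:100) {
    xy <- dsdn:::with_seed(seed, matrix(rnorm(40), 20, 2))
    expect_equal(pearson_r(xy[, 1], xy[, 2])$r,
                 pearson_oracle(xy[, 1], xy[, 2]), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("network similarity matrices are symmetric with unit diagonal and find planted factors", {
  obs <- dsdn:::with_seed(12, {
    m <- matrix(rnorm(30 * 7), 30, 7)
    colnames(m) <- network_names()
    m
  })
  sim <- network_similarity_matrix(tibble::as_tibble(obs))
  expect_equal(sim$r, t(sim$r))
  expect_equal(diag(sim$r), setNames(rep(1, 7), network_names()))
  expect_true(all(abs(sim$r) <= 1))
  dup <- tibble::as_tibble(obs)
  dup$SMN <- dup$VN
  sim_dup <- network_similarity_matrix(dup)
  expect_equal(sim_dup$r["VN", "SMN"], 1)
  hits <- 0
  for (seed in 1:100) {
    m <- dsdn:::with_seed(200 + seed, {
      z <- rnorm(30)
      m <- matrix(rnorm(30 * 7), 30, 7)
      colnames(m) <- network_names()
      m[, "DAN"] <- 0.8 * z + sqrt(1 - 0.64) * rnorm(30)
      m[, "VAN"] <- 0.8 * z + sqrt(1 - 0.64) * rnorm(30)
      m
    })
    s <- network_similarity_matrix(tibble::as_tibble(m))
    rdv <- s$r["DAN", "VAN"]
    others <- s$r[upper.tri(s$r)]
    others <- others[others != rdv]
    hits <- hits + (rdv > max(others))
  }
  expect_gte(hits, 95)
  const <- tibble::as_tibble(obs)
  const$VN <- 1
  expect_error(network_similarity_matrix(const), "constant")
})

test_that("slice similarity correlates within planes and reports unusable slices", {
  geom <- grid_geometry(c(4, 4, 2), mask_idx = 1:32)
  co <- dsdn:::voxel_coords(geom)
  ds <- dplyr::mutate(co, ds = dsdn:::with_seed(13, rnorm(32)))
  dn_affine <- dplyr::mutate(co, dn = 3 * ds$ds + 2)
  out <- slice_similarity(ds, dn_affine, geom)
  expect_equal(nrow(out), 2L)
  expect_equal(out$r, c(1, 1), tolerance = 1e-12)
  # hand-computed per-slice correlation
  dn_rand <- dplyr::mutate(co, dn = dsdn:::with_seed(14, rnorm(32)))
  out2 <- slice_similarity(ds, dn_rand, geom)
  for (sl in 1:2) {
    sel <- co$k == sl
    expect_equal(out2$r[sl], pearson_oracle(ds$ds[sel], dn_rand$dn[sel]),
                 tolerance = 1e-12)
  }
  # independent maps across many seeds: mean |r| stays small (64-voxel slices)
  geom8 <- grid_geometry(c(8, 8, 1), mask_idx = 1:64)
  co8 <- dsdn:::voxel_coords(geom8)
  rs <- vapply(1:100, function(seed) {
    a <- dplyr::mutate(co8, ds = dsdn:::with_seed(seed, rnorm(64)))
    b <- dplyr::mutate(co8, dn = dsdn:::with_seed(5000 + seed, rnorm(64)))
    slice_similarity(a, b, geom8)$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
})
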
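# Quartile-fence classification, overlap maps, network percentages, KDE.

test_that("quartile fences match hand values and a sort-and-interpolate oracle", {
  f <- quartile_fences(1:8)
  expect_equal(f$q1, 2.75)
  expect_equal(f$q3, 6.25)
  expect_equal(f$upper, 11.5)
  expect_equal(f$lower, -2.5)
  fc <- quartile_fences(rep(4, 10))
  expect_equal(c(fc$q1, fc$q3, fc$upper, fc$lower), rep(4, 4))
  # type-7 oracle: linear interpolation at position 1 + (n-1)p
  interp_q <- function(v, p) {
    v <- sort(v)
    pos <- 1 + (length(v) - 1) * p
    lo <- floor(pos)
    v[lo] + (pos - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  v <- dsdn:::with_seed(2, runif(1000))
  f2 <- quartile_fences(v)
  expect_equal(f2$q1, interp_q(v, 0.25), tolerance = 1e-12)
  expect_equal(f2$q3, interp_q(v, 0.75), tolerance = 1e-12)
  expect_equal(f2$upper, f2$q3 + 1.5 * (f2$q3 - f2$q1), tolerance = 1e-12)
  expect_error(quartile_fences(1:3), "at least 4")
  expect_error(quartile_fences(c(1, 2, NA, 4)), "finite")
})

test_that("level boundaries follow the closed-right intervals and counts are exact", {
  v <- dsdn:::with_seed(3, runif(1000))
  f <- quartile_fences(v)
  cl <- classify_levels(v, fences = f)
  expect_equal(cl$level[which(v == f$q3)], factor(character(0), levels = levels(cl$level)))
  # insert an exact-Q3 value: boundary belongs to the lower interval
  cl2 <- classify_levels(c(f$q3, f$q1, v), fences = f)
  expect_equal(as.character(cl2$level[1]), "medium")
  expect_equal(as.character(cl2$level[2]), "weak")
  # continuous map: exactly 250 of 1000 strong, 75% non-strong
  expect_equal(sum(cl$level == "strong"), 250L)
  expect_equal(mean(cl$level != "strong"), 0.75)
  expect_warning(cle <- classify_levels(rep(2, 10)), "medium")
  expect_true(all(cle$level == "medium"))
})

test_that("classification is invariant to monotone relabelling of voxel order", {
  v <- dsdn:::with_seed(4, rnorm(200))
  f <- quartile_fences(v)
  cl <- classify_levels(v, fences = f)
  perm <- dsdn:::with_seed(5, sample(200))
  clp <- classify_levels(v[perm], fences = f)
  expect_equal(as.character(clp$level), as.character(cl$level)[perm])
})

test_that("overlap categories partition the mask and percentages follow the denominator", {
  # strong sets {A,B,C} and {B,C,D} out of 8 voxels
  vds <- c(10, 9, 8, 1, 2, 3, 2, 1)   # strong: voxels 1,2,3
  vdn <- c(1, 9, 8, 10, 2, 3, 2, 1)   # strong: voxels 2,3,4
  f <- structure(list(q1 = 2, q3 = 7, iqr = 5, upper = 14.5, lower = -5.5),
                 class = "quartile_fences")
  ov <- strong_overlap(classify_levels(vds, fences = f),
                       classify_levels(vdn, fences = f))
  expect_equal(as.vector(table(ov$category)), c(4L, 1L, 1L, 2L))
  pct <- attr(ov, "percentages")
  expect_equal(pct$pct[pct$category == "both"], 50)
  expect_equal(pct$pct[pct$category == "ds_only"], 25)
  expect_equal(pct$pct[pct$category == "dn_only"], 25)
  expect_equal(sum(pct$pct), 100, tolerance = 1e-9)
  # identical strong sets -> both 100%; disjoint -> both 0%
  ov_same <- strong_overlap(classify_levels(vds, fences = f),
                            classify_levels(vds, fences = f))
  expect_equal(attr(ov_same, "percentages")$pct, c(100, 0, 0))
  vdis <- c(1, 2, 3, 10, 9, 8, 2, 1)
  ov_dis <- strong_overlap(classify_levels(vds, fences = f),
                           classify_levels(vdis, fences = f))
  expect_equal(attr(ov_dis, "percentages")$pct[1], 0)
  # mask denominator rescales but keeps the partition
  ov_mask <- strong_overlap(classify_levels(vds, fences = f),
                            classify_levels(vdn, fences = f),
                            denominator = "mask")
  expect_equal(attr(ov_mask, "percentages")$pct, 100 * c(2, 1, 1) / 8)
  expect_error(strong_overlap(classify_levels(vds, fences = f),
                              classify_levels(vdn[1:5], fences = f)),
               "differ")
})

test_that("network percentages of strong voxels sum to 100 and match planted counts", {
  networks <- tibble::tibble(
    voxel = 1:40,
    network = factor(c(rep("VN", 30), rep("FPN", 10)),
                     levels = c(network_names(), "none")))
  vals <- c(rep(10, 30), rep(10, 10))  # all strong
  f <- structure(list(q1 = 1, q3 = 5, iqr = 4, upper = 11, lower = -5),
                 class = "quartile_fences")
  cl <- classify_levels(vals, fences = f)
  tab <- network_strong_percentages(cl, networks)
  expect_equal(tab$pct[tab$network == "VN"], 75)
  expect_equal(tab$pct[tab$network == "FPN"], 25)
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  # all strong voxels in one network
  networks$network[] <- factor("DMN", levels = levels(networks$network))
  tab2 <- network_strong_percentages(cl, networks)
  expect_equal(tab2$pct[tab2$network == "DMN"], 100)
  expect_equal(sum(tab2$pct[tab2$network != "DMN"]), 0)
  cl_none <- classify_levels(rep(c(1, 2, 3, 4), 10), fences = f)
  expect_error(network_strong_percentages(cl_none, networks), "empty strong set")
})

test_that("kernel density integrates to one, is symmetric, and matches the kernel-sum oracle", {
  v <- dsdn:::with_seed(6, rnorm(400))
  d <- density_estimate(v)
  expect_equal(nrow(d), 512L)
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  h <- stats::bw.nrd0(v)
  idx <- round(seq(1, 512, length.out = 20))
  expect_equal(d$density[idx],
               vapply(d$x[idx], function(g) mean(stats::dnorm(g, v, h)),
                      numeric(1)),
               tolerance = 1e-10)
  two <- density_estimate(c(-1, 1), bw = 0.5)
  expect_lt(max(abs(two$density - rev(two$density))), 1e-10)
  expect_error(density_estimate(rep(1, 5)), "distinct")
})
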
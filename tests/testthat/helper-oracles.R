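# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each quantity with the most
# literal possible implementation, sharing no code with the package paths
# they check.

# Exhaustive DVV curve: explicit double loops over all delay-vector pairs
# and all neighbourhood sets.
dvv_oracle <- function(x, m, n_d, n_spans, t0) {
  x <- (x - mean(x)) / sd(x)
  n <- length(x)
  ndv <- n - m
  dvs <- sapply(seq_len(m), function(t) x[t:(t + ndv - 1)])
  targets <- x[(m + 1):n]
  D <- matrix(0, ndv, ndv)
  for (i in seq_len(ndv)) {
    for (j in seq_len(ndv)) {
      D[i, j] <- sqrt(sum((dvs[i, ] - dvs[j, ])^2))
    }
  }
  dd <- D[upper.tri(D)]
  mu <- mean(dd)
  sdv <- sqrt(mean((dd - mu)^2))
  lo <- max(0, mu - n_d * sdv)
  hi <- mu + n_d * sdv
  spans <- lo + (0:(n_spans - 1)) * ((hi - lo) / (n_spans - 1))
  sstar <- rep(NA_real_, n_spans)
  valid <- logical(n_spans)
  for (s in seq_along(spans)) {
    vars <- c()
    for (k in seq_len(ndv)) {
      mem <- which(D[k, ] <= spans[s])
      if (length(mem) >= t0 && length(mem) >= 2) {
        vars <- c(vars, var(targets[mem]))
      }
    }
    if (length(vars)) {
      sstar[s] <- mean(vars) / var(x)
      valid[s] <- TRUE
    }
  }
  list(spans = spans, sigma_star = sstar, valid = valid, mu_d = mu, sd_d = sdv)
}

# Two-way ANOVA ICC via the direct residual decomposition
icc_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  bms <- k * sum((rm_ - g)^2) / (n - 1)
  wss <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      wss <- wss + (x[i, j] - rm_[i] - cm_[j] + g)^2
    }
  }
  ems <- wss / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

# Welch t from the textbook formula
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson r from the covariance formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# random band-limited signal for EMD exercises
random_band_signal <- function(n, seed, tr = 2) {
  dsdn:::with_seed(seed, {
    x <- rnorm(n)
    dsdn:::bp_single(x, tr, 0.009, 0.08)
  })
}

# fmri_series from a bare matrix on a V x 1 x 1 grid
series_from_matrix <- function(values, tr = 2) {
  v <- nrow(values)
  geom <- grid_geometry(c(v, 1, 1), mask_idx = seq_len(v))
  fmri_series(values, geom, tr)
}

# logistic map series, standardised
logistic_signal <- function(n, seed) {
  dsdn:::with_seed(seed, {
    v <- numeric(n + 100)
    v[1] <- runif(1, 0.1, 0.9)
    for (i in seq_len(n + 99)) v[i + 1] <- 4 * v[i] * (1 - v[i])
    z <- v[101:(n + 100)]
    (z - mean(z)) / sd(z)
  })
}
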
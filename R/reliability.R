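# Test-retest reliability: two-way ANOVA intraclass correlation.

#' Consistency ICC from a subject-by-session panel
#'
#' Two-way ANOVA with random subject effects and fixed session effects
#' (the session sum of squares is removed from error), giving
#' `ICC = (BMS - EMS) / (BMS + (k - 1) EMS)` — the consistency form
#' ICC(3,1). `BMS` is the between-subjects mean square and `EMS` the
#' residual mean square with `(n-1)(k-1)` degrees of freedom. The F test is
#' `BMS / EMS` on `(n-1, (n-1)(k-1))` degrees of freedom, right tail.
#' Negative ICCs are reported as computed, not clipped.
#'
#' @param values Numeric `n x k` matrix (subjects by sessions), `n >= 2`,
#'   `k >= 2`, all finite. A data frame of the same shape is accepted.
#' @return Object of class `icc_result`: list with `icc`, `bms`, `ems`,
#'   `jms` (session mean square), `f_stat`, `df1`, `df2`, `p_value`, `n`,
#'   `k`, and `defined` (`FALSE` when there is no variance anywhere, in
#'   which case `icc` is `NA`).
#' @export
icc_consistency <- function(values) {
  x <- as.matrix(values)
  if (!is.numeric(x) || !all(is.finite(x))) abort("panel must be finite numeric")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) abort("panel needs at least 2 subjects and 2 sessions")
  grand <- mean(x)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_sess <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_res <- ss_tot - ss_subj - ss_sess
  bms <- ss_subj / (n - 1)
  jms <- ss_sess / (k - 1)
  ems <- ss_res / ((n - 1) * (k - 1))
  denom <- bms + (k - 1) * ems
  defined <- denom > 0
  icc <- if (defined) (bms - ems) / denom else NA_real_
  f_stat <- if (ems > 0) bms / ems else if (bms > 0) Inf else NA_real_
  p_value <- if (is.na(f_stat)) NA_real_ else {
    pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, bms = bms, ems = ems, jms = jms,
                 f_stat = f_stat, df1 = n - 1L, df2 = (n - 1L) * (k - 1L),
                 p_value = p_value, n = n, k = k, defined = defined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (!x$defined) {
    cat("<icc_result> undefined (no variance anywhere)\n")
  } else {
    cat(sprintf("<icc_result> ICC = %.4f (n = %d, k = %d), F(%d, %d) = %.3g, p = %.3g\n",
                x$icc, x$n, x$k, x$df1, x$df2, x$f_stat, x$p_value))
  }
  invisible(x)
}

#' @rdname icc_consistency
#' @param x An `icc_result`.
#' @param ... Unused.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(term = c("subjects", "sessions", "residual"),
         mean_square = c(x$bms, x$jms, x$ems),
         df = c(x$df1, x$k - 1L, x$df2))
}

#' @rdname icc_consistency
#' @param x An `icc_result`.
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, bms = x$bms, ems = x$ems, f_stat = x$f_stat,
         df1 = x$df1, df2 = x$df2, p_value = x$p_value, n = x$n, k = x$k)
}

#' Voxel-wise ICC map from per-scan value maps
#'
#' Computes [icc_consistency()] per voxel from a long panel of per-scan
#' values, vectorised across voxels. Voxels significant at `alpha` are
#' flagged.
#'
#' @param panel Long tibble with columns `subject`, `session`, `voxel`,
#'   `value`; every voxel must have a complete subject-by-session panel.
#' @param alpha Significance threshold for the companion flag
#'   (default 0.05).
#' @param adjust Multiple-testing adjustment for the significance flag, a
#'   [stats::p.adjust()] method; `"none"` (the default) flags on the raw
#'   p-values, `"BH"` applies Benjamini-Hochberg across voxels. The
#'   reported `p_value` column is always unadjusted.
#' @return Tibble with `voxel`, `icc`, `bms`, `ems`, `f_stat`, `p_value`,
#'   `significant`.
#' @export
icc_map <- function(panel, alpha = 0.05, adjust = "none") {
  need <- c("subject", "session", "voxel", "value")
  if (!all(need %in% names(panel))) {
    abort("`panel` needs columns subject, session, voxel, value")
  }
  subjects <- sort(unique(panel$subject))
  sessions <- sort(unique(panel$session))
  voxels <- sort(unique(panel$voxel))
  n <- length(subjects)
  k <- length(sessions)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 sessions")
  if (nrow(panel) != n * k * length(voxels) || anyNA(panel$value)) {
    abort("misaligned maps: panel is not complete over subject x session x voxel")
  }
  # (n*k) x V matrix, subject fastest within session
  ord <- order(panel$voxel, match(panel$session, sessions),
               match(panel$subject, subjects))
  m <- matrix(panel$value[ord], n * k, length(voxels))
  grand <- colMeans(m)
  subj_means <- rowsum(m, rep(seq_len(n), times = k)) / k
  sess_means <- rowsum(m, rep(seq_len(k), each = n)) / n
  ss_subj <- k * colSums(sweep(subj_means, 2, grand)^2)
  ss_sess <- n * colSums(sweep(sess_means, 2, grand)^2)
  ss_tot <- colSums(sweep(m, 2, grand)^2)
  ss_res <- pmax(ss_tot - ss_subj - ss_sess, 0)
  bms <- ss_subj / (n - 1)
  ems <- ss_res / ((n - 1) * (k - 1))
  denom <- bms + (k - 1) * ems
  icc <- ifelse(denom > 0, (bms - ems) / denom, NA_real_)
  f_stat <- ifelse(ems > 0, bms / ems, ifelse(bms > 0, Inf, NA_real_))
  p_value <- pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  p_flag <- stats::p.adjust(p_value, method = adjust)
  tibble(voxel = voxels, icc = icc, bms = bms, ems = ems,
         f_stat = f_stat, p_value = p_value,
         significant = !is.na(p_flag) & p_flag < alpha)
}

#' Two-sample t test between networks
#'
#' Welch's unequal-variance t by default (`pooled = TRUE` for the classical
#' pooled-variance form), two-sided.
#'
#' @param a,b Numeric samples, each with at least 2 values and nonzero
#'   combined variance.
#' @param pooled Use the pooled-variance t instead of Welch.
#' @return Tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs at least 2 values")
  if (var(a) + var(b) == 0) abort("degenerate variance: both samples constant")
  ht <- stats::t.test(a, b, var.equal = pooled)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Equal-length numeric samples (n >= 3), both non-constant.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("samples must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
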
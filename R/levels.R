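# Quartile-fence thresholding, overlap maps, network percentages, KDE.

#' Quartile fences of a value distribution
#'
#' Quartiles by linear interpolation of order statistics (quantile type 7,
#' position `1 + (n-1)p`); fences are `Q3 + 1.5*IQR` (upper) and
#' `Q1 - 1.5*IQR` (lower). The third quartile is the threshold for the
#' strong level.
#'
#' @param values Finite numeric vector, length >= 4.
#' @param probs Lower/upper quantile pair defining the "quartiles"
#'   (default `c(0.25, 0.75)`); exposed so the strong threshold can be
#'   moved off the third quartile.
#' @return Object of class `quartile_fences`: list with `q1`, `q3`, `iqr`,
#'   `upper`, `lower`.
#' @export
quartile_fences <- function(values, probs = c(0.25, 0.75)) {
  values <- as.numeric(values)
  if (length(values) < 4L) abort("need at least 4 values for quartile fences")
  if (!is_finite_vector(values)) abort("non-finite values present")
  if (length(probs) != 2L || probs[1] >= probs[2]) abort("`probs` must be an increasing pair")
  q <- unname(quantile(values, probs, type = 7))
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 upper = q[2] + 1.5 * iqr, lower = q[1] - 1.5 * iqr),
            class = "quartile_fences")
}

#' @export
print.quartile_fences <- function(x, ...) {
  cat(sprintf("<quartile_fences> Q1 = %.4g, Q3 = %.4g, fences [%.4g, %.4g]\n",
              x$q1, x$q3, x$lower, x$upper))
  invisible(x)
}

#' @rdname quartile_fences
#' @param x A `quartile_fences`.
#' @param ... Unused.
#' @method tidy quartile_fences
#' @export
tidy.quartile_fences <- function(x, ...) {
  tibble(q1 = x$q1, q3 = x$q3, iqr = x$iqr,
         lower = x$lower, upper = x$upper)
}

#' Classify per-voxel values into weak/medium/strong levels
#'
#' Levels by the quartile scheme: weak for `value <= Q1`, medium for
#' `Q1 < value <= Q3` (a value exactly at a quartile belongs to the lower
#' interval), strong for `value > Q3`. Values beyond the outer fences stay
#' weak/strong respectively but are counted and reported with a warning
#' (long-tailed distributions routinely exceed the upper fence).
#'
#' @param data Data frame with one row per voxel (e.g. a [ds_map()]
#'   result), or a bare numeric vector.
#' @param value Column holding the values (tidy-eval), default `ds` if
#'   present else the first numeric column after `voxel`/`i`/`j`/`k`.
#' @param fences A [quartile_fences()]; computed from the data when `NULL`.
#'   Pass fences from a reference (e.g. group-average) distribution to
#'   classify per-scan maps against a common threshold.
#' @return Object of class `level_classification`: the input tibble with a
#'   `level` factor column (`weak`, `medium`, `strong`), plus attributes
#'   `fences` and `out_of_fence_count`. All-equal inputs classify as all
#'   medium with a warning.
#' @export
classify_levels <- function(data, value = NULL, fences = NULL) {
  if (is.numeric(data)) data <- tibble(value = as.numeric(data))
  data <- as_tibble(data)
  value_quo <- rlang::enquo(value)
  col <- if (!rlang::quo_is_null(value_quo)) {
    rlang::as_name(value_quo)
  } else if ("value" %in% names(data)) "value"
  else if ("ds" %in% names(data)) "ds"
  else if ("dn" %in% names(data)) "dn"
  else abort("no value column found; pass `value`")
  v <- data[[col]]
  if (!is.numeric(v)) abort(sprintf("column `%s` is not numeric", col))
  keep <- is.finite(v)
  fences <- fences %||% quartile_fences(v[keep])
  if (!inherits(fences, "quartile_fences")) abort("`fences` must be quartile_fences")
  lev <- rep(NA_character_, length(v))
  if (fences$iqr == 0) {
    warn("degenerate distribution (Q1 = Q3): all values classified medium")
    lev[keep] <- "medium"
  } else {
    lev[keep] <- dplyr::case_when(v[keep] <= fences$q1 ~ "weak",
                                  v[keep] <= fences$q3 ~ "medium",
                                  TRUE ~ "strong")
  }
  oof <- sum(keep & (v < fences$lower | v > fences$upper))
  if (oof > 0) {
    warn(sprintf("%d values outside the [lower, upper] fences (kept as weak/strong)", oof))
  }
  out <- dplyr::mutate(data, level = factor(lev, levels = c("weak", "medium", "strong")))
  structure(out, class = c("level_classification", class(out)),
            fences = fences, out_of_fence_count = oof, value_col = col)
}

level_of <- function(class) {
  if (!inherits(class, "level_classification")) {
    abort("expected a `level_classification`")
  }
  class$level
}

#' DS-by-DN strong-level overlap map
#'
#' Crosses two level classifications over the same voxels into four
#' categories: `neither`, `ds_only`, `dn_only`, `both` (strong in both).
#' Percentages of `both`/`ds_only`/`dn_only` are reported relative to the
#' chosen denominator: the union of the two strong sets (default) or the
#' whole mask.
#'
#' @param class_ds,class_dn [classify_levels()] results over identical
#'   voxel sets (DS first, DN second).
#' @param denominator `"union"` (default) or `"mask"`.
#' @return Object of class `overlap_map`: tibble with voxel columns and
#'   `category` factor, plus attribute `percentages` (tibble of `category`,
#'   `n`, `pct`) and `denominator`.
#' @export
strong_overlap <- function(class_ds, class_dn, denominator = c("union", "mask")) {
  denominator <- match.arg(denominator)
  lds <- level_of(class_ds)
  ldn <- level_of(class_dn)
  if (length(lds) != length(ldn)) abort("voxel sets differ between the two classifications")
  if ("voxel" %in% names(class_ds) && "voxel" %in% names(class_dn) &&
      !identical(class_ds$voxel, class_dn$voxel)) {
    abort("voxel sets differ between the two classifications")
  }
  s_ds <- !is.na(lds) & lds == "strong"
  s_dn <- !is.na(ldn) & ldn == "strong"
  cat_ <- dplyr::case_when(s_ds & s_dn ~ "both",
                           s_ds ~ "ds_only",
                           s_dn ~ "dn_only",
                           TRUE ~ "neither")
  category <- factor(cat_, levels = c("neither", "ds_only", "dn_only", "both"))
  denom <- switch(denominator, union = sum(s_ds | s_dn), mask = length(lds))
  if (denom == 0) abort("empty strong sets: no voxels to form percentages")
  pct <- tibble(category = factor(c("both", "ds_only", "dn_only"),
                                  levels = levels(category)),
                n = c(sum(s_ds & s_dn), sum(s_ds & !s_dn), sum(!s_ds & s_dn))) |>
    dplyr::mutate(pct = 100 * .data$n / denom)
  base <- if ("voxel" %in% names(class_ds)) {
    dplyr::select(as_tibble(class_ds), dplyr::any_of(c("voxel", "i", "j", "k")))
  } else {
    tibble(voxel = seq_along(lds))
  }
  out <- dplyr::mutate(base, category = category)
  structure(out, class = c("overlap_map", class(out)),
            percentages = pct, denominator = denominator)
}

#' @rdname strong_overlap
#' @param x An `overlap_map`.
#' @param ... Unused.
#' @method glance overlap_map
#' @export
glance.overlap_map <- function(x, ...) {
  tidyr::pivot_wider(attr(x, "percentages")[, c("category", "pct")],
                     names_from = "category", values_from = "pct")
}

#' Per-network share of strong voxels
#'
#' For a level classification (its strong voxels) or an overlap map (its
#' `both` voxels), the percentage of those voxels falling in each of the
#' seven networks; percentages over labelled voxels sum to 100.
#'
#' @param class A `level_classification` or `overlap_map`.
#' @param networks Tibble from [atlas_networks()] (columns `voxel`,
#'   `network`) aligned with the map.
#' @return Tibble with `network`, `n`, `pct`.
#' @export
network_strong_percentages <- function(class, networks) {
  sel <- if (inherits(class, "overlap_map")) {
    class$category == "both"
  } else {
    lv <- level_of(class)
    !is.na(lv) & lv == "strong"
  }
  if (length(sel) != nrow(networks)) abort("atlas not aligned to the map")
  if (!any(sel)) abort("empty strong set")
  net <- networks$network[sel]
  net <- net[net != "none"]
  counts <- table(factor(net, levels = network_names()))
  tibble(network = factor(network_names(), levels = network_names()),
         n = as.integer(counts),
         pct = 100 * as.integer(counts) / sum(counts))
}

#' Gaussian kernel density of a value map
#'
#' Exact Gaussian kernel sum (no binning approximation) on a 512-point
#' grid spanning the data plus three bandwidths on each side; for
#' well-behaved unimodal maps the trapezoid integral is 1 to within 1e-3.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @param bw Bandwidth: a number, or `"nrd0"` for Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]).
#' @return Tibble with `x` (grid) and `density`.
#' @export
density_estimate <- function(values, bw = "nrd0") {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) abort("need at least 2 distinct values for a density")
  h <- if (identical(bw, "nrd0")) stats::bw.nrd0(values) else {
    check_scalar_number(bw, "bw", lower = 1e-12)
    bw
  }
  grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = values, sd = h)),
                 numeric(1))
  tibble(x = grid, density = dens)
}
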
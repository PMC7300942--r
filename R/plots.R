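# ggplot2 visualisation methods for result objects.

#' @rdname degree_of_nonlinearity
#' @method autoplot dvv_result
#' @export
autoplot.dvv_result <- function(object, ...) {
  d <- object$curve |>
    tidyr::pivot_longer(c("sigma_star", "surrogate_mean"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         sigma_star = "original",
                                         surrogate_mean = "surrogate mean"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$span, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(tau[d] ~ "(standardised distance)"),
                  y = expression(sigma^{"*2"}),
                  title = sprintf("DVV curves, DN = %.3g", object$dn),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname degree_of_stationarity
#' @method autoplot ds_profile
#' @export
autoplot.ds_profile <- function(object, ...) {
  d <- dplyr::filter(object$by_freq, .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$freq_lo + .data$freq_hi) / 2,
                                  y = .data$ds)) +
    ggplot2::geom_col(width = d$freq_hi - d$freq_lo, fill = "steelblue") +
    ggplot2::labs(x = "frequency (cycles/sample)", y = "DS(w)",
                  title = sprintf("Degree of stationarity, scalar DS = %.3g",
                                  object$ds_scalar)) +
    ggplot2::theme_minimal()
}

#' @rdname network_similarity_matrix
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  d <- tidyr::crossing(network_a = rownames(object$r),
                       network_b = colnames(object$r)) |>
    dplyr::mutate(r = as.vector(t(object$r)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$network_a, y = .data$network_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a per-voxel map
#'
#' @param map Tibble with `i`, `j`, `k` and a value column (e.g. a
#'   [ds_map()] result).
#' @param value Column to plot (tidy-eval), default `ds` or `dn`.
#' @param slice Slice index along the third axis (default: middle slice).
#' @return A ggplot object.
#' @export
plot_voxel_slice <- function(map, value = NULL, slice = NULL) {
  value_quo <- rlang::enquo(value)
  col <- if (!rlang::quo_is_null(value_quo)) rlang::as_name(value_quo)
  else intersect(c("ds", "dn", "icc", "value"), names(map))[1]
  if (is.na(col)) abort("no value column found; pass `value`")
  slice <- slice %||% sort(unique(map$k))[ceiling(length(unique(map$k)) / 2)]
  d <- dplyr::filter(map, .data$k == slice)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s, slice k = %d", col, slice)) +
    ggplot2::theme_minimal()
}
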
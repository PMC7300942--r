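# Similarity of DS/DN across networks and axial slices.

#' Between-network similarity matrix
#'
#' Pearson correlation between per-network mean values across
#' subject-by-session observations: each observation (scan) contributes one
#' mean value per network, and networks are correlated column-wise.
#'
#' @param data Either a long tibble with columns `network`, `value` plus
#'   observation identifiers (e.g. `subject`, `session`), or a wide data
#'   frame with one column per network.
#' @return Object of class `similarity_matrix`: list with `r` and `p`
#'   (symmetric network x network matrices, unit/NA diagonal) and `n`
#'   observations.
#' @export
network_similarity_matrix <- function(data) {
  wide <- if ("network" %in% names(data) && "value" %in% names(data)) {
    tidyr::pivot_wider(as_tibble(data), names_from = "network",
                       values_from = "value")
  } else {
    as_tibble(data)
  }
  nets <- intersect(network_names(), names(wide))
  if (length(nets) < 2L) abort("need at least 2 network columns")
  m <- as.matrix(wide[, nets])
  if (!is.numeric(m) || anyNA(m)) abort("network values must be complete and numeric")
  if (nrow(m) < 3L) abort("need at least 3 observations per network")
  if (any(apply(m, 2, sd) == 0)) {
    abort(sprintf("constant network column(s): %s",
                  paste(nets[apply(m, 2, sd) == 0], collapse = ", ")))
  }
  r <- p <- matrix(NA_real_, length(nets), length(nets),
                   dimnames = list(nets, nets))
  diag(r) <- 1
  for (a in seq_along(nets)) {
    for (b in seq_len(a - 1L)) {
      pr <- pearson_r(m[, a], m[, b])
      r[a, b] <- r[b, a] <- pr$r
      p[a, b] <- p[b, a] <- pr$p_value
    }
  }
  structure(list(r = r, p = p, n = nrow(m)), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d networks, %d observations\n",
              nrow(x$r), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname network_similarity_matrix
#' @param x A `similarity_matrix` (tidiers) or plot object.
#' @param ... Unused.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  nets <- rownames(x$r)
  tidyr::crossing(network_a = nets, network_b = nets) |>
    dplyr::mutate(r = as.vector(t(x$r)),
                  p_value = as.vector(t(x$p))) |>
    dplyr::filter(.data$network_a < .data$network_b)
}

#' DS-DN correlation within each axial slice
#'
#' Correlates the DS and DN values of in-mask voxels within each plane
#' along the geometry's slice axis. Slices with fewer than 3 usable voxels
#' (finite in both maps) or a constant map are reported with `NA`.
#'
#' @param ds_map,dn_map Tibbles with `voxel`, `i`, `j`, `k` and a `ds` /
#'   `dn` column, over identical voxel sets (e.g. [ds_map()] / [dn_map()]
#'   output).
#' @param geometry The [grid_geometry()] the maps live on (provides
#'   `slice_axis`).
#' @return Tibble with `slice`, `n_voxels`, `r`, `p_value`.
#' @export
slice_similarity <- function(ds_map, dn_map, geometry) {
  if (!identical(ds_map$voxel, dn_map$voxel)) abort("maps are not aligned")
  axis_col <- c("i", "j", "k")[geometry$slice_axis]
  joined <- tibble(slice = ds_map[[axis_col]], ds = ds_map$ds, dn = dn_map$dn)
  out <- joined |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(
      n_voxels = sum(is.finite(.data$ds) & is.finite(.data$dn)),
      r = {
        ok <- is.finite(.data$ds) & is.finite(.data$dn)
        if (sum(ok) >= 3 && sd(.data$ds[ok]) > 0 && sd(.data$dn[ok]) > 0) {
          pearson_r(.data$ds[ok], .data$dn[ok])$r
        } else NA_real_
      },
      p_value = {
        ok <- is.finite(.data$ds) & is.finite(.data$dn)
        if (sum(ok) >= 3 && sd(.data$ds[ok]) > 0 && sd(.data$dn[ok]) > 0) {
          pearson_r(.data$ds[ok], .data$dn[ok])$p_value
        } else NA_real_
      },
      .groups = "drop")
  if (all(is.na(out$r))) abort("no valid slices (each needs >= 3 usable voxels)")
  out
}
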
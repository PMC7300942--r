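#' Grid geometry of a volumetric acquisition
#'
#' Records the voxel grid shape, physical voxel size, the voxel-to-world
#' affine, the axial slice axis used for slice-wise analyses, and the linear
#' indices of in-mask voxels. Voxel order throughout the package is ascending
#' linear index with the first axis fastest (R array order), so any per-voxel
#' vector, tibble or map row `v` always refers to the same grid location.
#'
#' @param dims Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size Numeric length 3, mm per axis.
#' @param affine 4x4 voxel-to-world matrix; defaults to a scaling by
#'   `voxel_size`. Must be invertible.
#' @param slice_axis Index (1-3) of the axis treated as axial for slice-wise
#'   similarity analysis.
#' @param mask_idx Integer vector of linear indices of in-mask voxels, in
#'   ascending order.
#' @param ref Optional reference NIfTI header used when writing maps.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims, voxel_size = c(4, 4, 4), affine = NULL,
                          slice_axis = 3L, mask_idx = integer(), ref = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    abort("`dims` must be 3 positive integers")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 positive lengths (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    abort("`affine` must be an invertible 4x4 matrix")
  }
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) abort("`slice_axis` must be 1, 2 or 3")
  mask_idx <- sort(unique(as.integer(mask_idx)))
  if (length(mask_idx) && (min(mask_idx) < 1L || max(mask_idx) > prod(dims))) {
    abort("`mask_idx` out of grid range")
  }
  structure(
    list(dims = dims, voxel_size = as.numeric(voxel_size), affine = affine,
         slice_axis = slice_axis, mask_idx = mask_idx, ref = ref),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s grid, %s mm voxels, %d in-mask voxels\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              length(x$mask_idx)))
  invisible(x)
}

# tibble of 1-based grid coordinates for the in-mask voxels, in voxel order
voxel_coords <- function(geometry) {
  ijk <- arrayInd(geometry$mask_idx, geometry$dims)
  tibble(voxel = seq_along(geometry$mask_idx),
         i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L])
}

affines_match <- function(a, b, tol = 1e-4) {
  max(abs(as.matrix(a) - as.matrix(b))) <= tol
}

#' Masked voxel-by-time series container
#'
#' Holds a V x N matrix of in-mask voxel time series (one row per voxel in
#' the documented ascending-linear-index order), the grid geometry, and the
#' sampling interval (TR, seconds).
#'
#' @param values Numeric V x N matrix, all entries finite.
#' @param geometry A [grid_geometry()] whose `mask_idx` has V entries.
#' @param tr Sampling interval in seconds (> 0).
#' @return An object of class `fmri_series`.
#' @export
fmri_series <- function(values, geometry, tr) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || !all(is.finite(values))) {
    abort("`values` must be a finite numeric matrix")
  }
  if (!inherits(geometry, "grid_geometry")) abort("`geometry` must be a grid_geometry")
  if (nrow(values) != length(geometry$mask_idx)) {
    abort(sprintf("row count (%d) does not match mask size (%d)",
                  nrow(values), length(geometry$mask_idx)))
  }
  check_scalar_number(tr, "tr", lower = 1e-6)
  structure(list(values = values, geometry = geometry, tr = as.numeric(tr)),
            class = "fmri_series")
}

#' @export
print.fmri_series <- function(x, ...) {
  cat(sprintf("<fmri_series> %d voxels x %d timepoints, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.fmri_series <- function(x) dim(x$values)

#' @rdname fmri_series
#' @param x An `fmri_series`.
#' @param ... Unused.
#' @method as_tibble fmri_series
#' @export
as_tibble.fmri_series <- function(x, ...) {
  co <- voxel_coords(x$geometry)
  vals <- x$values
  tidyr::crossing(co, time = seq_len(ncol(vals))) |>
    dplyr::arrange(.data$voxel, .data$time) |>
    dplyr::mutate(value = as.vector(t(vals)))
}
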
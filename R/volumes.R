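# NIfTI input/output: series extraction, map writing, atlas handling.

#' Read a 4-D NIfTI series under a binary mask
#'
#' Extracts one time series per nonzero mask voxel. Rows follow the package's
#' deterministic voxel order: ascending linear index with the first (x) axis
#' fastest, so repeated reads of identical files give identical matrices.
#'
#' @param path Path to a 4-D NIfTI image.
#' @param mask_path Path to a 3-D binary mask sharing grid and affine with
#'   `path` (affines compared with tolerance `1e-4`).
#' @param slice_axis Axis treated as axial for slice-wise analysis.
#' @return An [fmri_series()] whose `geometry` carries the mask indices and
#'   the source header (reused when writing maps).
#' @export
read_volume_series <- function(path, mask_path, slice_axis = 3L) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  d4 <- dim(img)
  if (length(d4) != 4L) abort(sprintf("`%s` is not a 4-D image", path))
  if (length(dim(msk)) != 3L) abort(sprintf("`%s` is not a 3-D mask", mask_path))
  if (!all(d4[1:3] == dim(msk))) {
    abort(sprintf("grid mismatch: image %s vs mask %s",
                  paste(d4[1:3], collapse = "x"), paste(dim(msk), collapse = "x")))
  }
  if (!affines_match(RNifti::xform(img), RNifti::xform(msk))) {
    abort("image and mask affines differ beyond tolerance 1e-4 (resampling is out of scope)")
  }
  mask_idx <- which(as.array(msk) != 0)
  if (length(mask_idx) == 0L) abort("empty mask: no nonzero voxels")
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  vals <- matrix(as.array(img), prod(d4[1:3]), d4[4])[mask_idx, , drop = FALSE]
  if (anyNA(vals) || !all(is.finite(vals))) {
    abort("non-finite voxel values inside the mask")
  }
  geom <- grid_geometry(d4[1:3], voxel_size = pd[1:3],
                        affine = RNifti::xform(img), slice_axis = slice_axis,
                        mask_idx = mask_idx, ref = RNifti::niftiHeader(img))
  fmri_series(vals, geom, tr)
}

#' Write a per-voxel map as a 3-D NIfTI volume
#'
#' Values are placed at the geometry's mask indices in the documented voxel
#' order; everything outside the mask is 0. `NA` values are written as 0 and
#' counted in a message.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param geometry A [grid_geometry()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(values, geometry, path) {
  if (!inherits(geometry, "grid_geometry")) abort("`geometry` must be a grid_geometry")
  values <- as.numeric(values)
  if (length(values) != length(geometry$mask_idx)) {
    abort(sprintf("value count (%d) does not match mask size (%d)",
                  length(values), length(geometry$mask_idx)))
  }
  n_na <- sum(!is.finite(values))
  if (n_na > 0) {
    inform(sprintf("%d non-finite values written as 0", n_na))
    values[!is.finite(values)] <- 0
  }
  if (all(values == 0)) warn("all values are zero: map is indistinguishable from background")
  arr <- array(0, geometry$dims)
  arr[geometry$mask_idx] <- values
  img <- if (!is.null(geometry$ref)) {
    RNifti::asNifti(arr, reference = geometry$ref)
  } else {
    out <- RNifti::asNifti(arr)
    RNifti::qform(out) <- structure(geometry$affine, code = 2L)
    RNifti::pixdim(out) <- geometry$voxel_size
    out
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' The seven-network label vocabulary
#'
#' Canonical cortical functional networks: visual (VN), somatomotor (SMN),
#' dorsal attention (DAN), ventral attention (VAN), limbic (LIMB),
#' frontoparietal (FPN), default-mode (DMN).
#'
#' @return Character vector of the seven network names.
#' @export
network_names <- function() c("VN", "SMN", "DAN", "VAN", "LIMB", "FPN", "DMN")

#' Default integer-to-network label mapping
#'
#' @return Named character vector mapping atlas integers 1..7 to networks.
#' @export
yeo7_label_map <- function() setNames(network_names(), as.character(1:7))

#' Load an integer-labelled network atlas volume
#'
#' @param path Path to a 3-D NIfTI label volume.
#' @param label_map Named character vector mapping the atlas' nonzero
#'   integers (as names) to network names; must cover every nonzero label
#'   present and map only into [network_names()].
#' @return An object of class `network_atlas` with the label array and map.
#' @export
load_network_atlas <- function(path, label_map = yeo7_label_map()) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort(sprintf("`%s` is not a 3-D label volume", path))
  labels <- round(as.array(img))
  present <- sort(unique(labels[labels != 0]))
  unmapped <- setdiff(as.character(present), names(label_map))
  if (length(unmapped)) {
    abort(sprintf("unmapped atlas labels present: %s", paste(unmapped, collapse = ", ")))
  }
  bad <- setdiff(unname(label_map), network_names())
  if (length(bad)) {
    abort(sprintf("label_map targets outside the 7-network vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(labels = labels, label_map = label_map,
                 affine = RNifti::xform(img)),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  tab <- table(factor(x$label_map[as.character(x$labels[x$labels != 0])],
                      levels = network_names()))
  cat("<network_atlas>", paste(dim(x$labels), collapse = "x"), "grid\n")
  print(tab)
  invisible(x)
}

#' Network label of each in-mask voxel
#'
#' @param atlas A [load_network_atlas()] result (or an object with the same
#'   shape, e.g. from the synthetic generator).
#' @param geometry A [grid_geometry()] aligned with the atlas.
#' @return Tibble with `voxel` and `network` (factor over the seven networks
#'   plus `"none"` for unlabelled in-mask voxels), in voxel order.
#' @export
atlas_networks <- function(atlas, geometry) {
  if (!inherits(atlas, "network_atlas")) abort("`atlas` must be a network_atlas")
  if (!all(dim(atlas$labels) == geometry$dims)) {
    abort("atlas grid does not match geometry")
  }
  code <- atlas$labels[geometry$mask_idx]
  net <- ifelse(code == 0, "none", unname(atlas$label_map[as.character(code)]))
  tibble(voxel = seq_along(code),
         network = factor(net, levels = c(network_names(), "none")))
}
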
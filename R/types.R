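# Lightweight S3 containers for the imaging side of the pipeline.
# Convention (fixed across the package): volume axis order is (z, y, x),
# voxel indices are 0-based in physical-coordinate formulas, and the
# physical coordinate of a voxel is index * spacing + origin.

#' Volume metadata
#'
#' @param spacing_um positive triple, voxel size in micrometers (z, y, x).
#' @param origin numeric triple, physical position of voxel (0,0,0) in um.
#' @param ct_units label for the scalar values; CT numbers are unitless.
#' @return an object of class `volume_meta`.
#' @export
volume_meta <- function(spacing_um = c(10, 10, 10), origin = c(0, 0, 0),
                        ct_units = "CT number") {
  assert_triple(spacing_um, "spacing_um", positive = TRUE)
  assert_triple(origin, "origin")
  structure(list(spacing_um = as.numeric(spacing_um),
                 origin = as.numeric(origin),
                 ct_units = ct_units),
            class = "volume_meta")
}

#' CT volume container
#'
#' @param voxels 3D numeric array of CT numbers, axis order (z, y, x).
#' @param meta a [volume_meta()] object.
#' @return an object of class `ct_volume` with fields `voxels` and `meta`.
#' @export
ct_volume <- function(voxels, meta = volume_meta()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_input("`voxels` must be a 3D array (axis order z, y, x)")
  if (!all(is.finite(voxels)))
    stop_input("`voxels` must be finite")
  structure(list(voxels = voxels, meta = meta), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing (%s) um, range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(x$meta$spacing_um, collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Paired regions of interest for threshold estimation
#'
#' The otolith ROI delimits the voxels containing the otolith spot (plus
#' whatever fluid an annotator would include); the tissue ROI samples the
#' surrounding soft tissue. The two must be disjoint, non-empty, and on the
#' same grid.
#'
#' @param otolith_roi,tissue_roi logical 3D arrays on the volume's grid.
#' @return an object of class `roi_pair`.
#' @export
roi_pair <- function(otolith_roi, tissue_roi) {
  for (nm in c("otolith_roi", "tissue_roi")) {
    m <- get(nm)
    if (!is.array(m) || length(dim(m)) != 3L)
      stop_input(sprintf("`%s` must be a 3D array", nm))
  }
  otolith_roi <- otolith_roi != 0
  tissue_roi <- tissue_roi != 0
  if (!identical(dim(otolith_roi), dim(tissue_roi)))
    stop_input("ROI masks must share one voxel grid")
  if (!any(otolith_roi) || !any(tissue_roi))
    stop_input("both ROIs must be non-empty")
  if (any(otolith_roi & tissue_roi))
    stop_input("otolith and tissue ROIs must be disjoint")
  structure(list(otolith_roi = otolith_roi, tissue_roi = tissue_roi),
            class = "roi_pair")
}

check_same_grid <- function(vol, mask, name = "mask") {
  if (!identical(dim(vol$voxels), dim(mask)))
    stop_input(sprintf("`%s` is not on the volume's voxel grid", name))
  invisible(TRUE)
}
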
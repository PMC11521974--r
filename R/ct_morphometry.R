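# Micro-CT quantification chain.
#
# The otolith is segmented inside its ROI at the midpoint threshold
# T = (alpha + beta) / 2, where alpha summarizes CT numbers in the otolith
# ROI and beta those in the surrounding-tissue ROI. Because the threshold
# is recomputed from each specimen's own ROIs, it adapts to per-specimen
# contrast. The striola edge statistic then counts the voxels gained when
# the threshold is relaxed to 0.9 T: the band 0.9 T <= CT < T sits on the
# CT-number slope flanking the striola, so its volume grows as the slope
# becomes gentler with age.

#' Histogram of CT numbers inside an ROI
#'
#' @param vol a [ct_volume()].
#' @param roi logical mask on the volume's grid; must be non-empty.
#' @param n_bins number of equal-width bins spanning the observed range.
#' @return list with `breaks` (length `n_bins + 1`), `counts`
#'   (length `n_bins`, summing to the ROI voxel count), and `mids`.
#' @export
roi_histogram <- function(vol, roi, n_bins = 256L) {
  check_same_grid(vol, roi, "roi")
  v <- vol$voxels[roi != 0]
  if (length(v) == 0L) stop_input("ROI is empty")
  if (n_bins < 1L) stop_input("`n_bins` must be >= 1")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2)
}

roi_summary <- function(vol, roi, summary) {
  v <- vol$voxels[roi]
  if (summary == "mean") return(mean(v))
  h <- roi_histogram(vol, roi != 0)
  h$mids[which.max(h$counts)]
}

#' Midpoint segmentation threshold from paired ROIs
#'
#' Computes alpha (otolith-ROI summary), beta (tissue-ROI summary), the
#' segmentation threshold `T = (alpha + beta) / 2`, and the lower bound of
#' the striola edge band, `0.9 * T`.
#'
#' @param vol a [ct_volume()].
#' @param rois a [roi_pair()].
#' @param summary how to summarize each ROI's CT numbers: the arithmetic
#'   `"mean"` (default; stable on small ROIs) or the histogram `"mode"`.
#' @return list of class `threshold_result` with `alpha`, `beta`,
#'   `threshold`, `edge_lower`, and `summary`.
#' @export
compute_threshold <- function(vol, rois, summary = c("mean", "mode")) {
  summary <- match.arg(summary)
  if (!inherits(rois, "roi_pair"))
    stop_input("`rois` must be a roi_pair")
  check_same_grid(vol, rois$otolith_roi, "otolith_roi")
  alpha <- roi_summary(vol, rois$otolith_roi, summary)
  beta <- roi_summary(vol, rois$tissue_roi, summary)
  if (alpha <= beta)
    stop_input(sprintf(
      "no contrast: otolith-ROI summary (%.4g) <= tissue-ROI summary (%.4g); ROIs swapped or degenerate?",
      alpha, beta))
  thr <- (alpha + beta) / 2
  structure(list(alpha = alpha, beta = beta, threshold = thr,
                 edge_lower = 0.9 * thr, summary = summary),
            class = "threshold_result")
}

# 26-connected component labelling of a 3D logical mask (breadth-first,
# vectorized over the BFS frontier). Returns an integer array of labels,
# 0 = background.
label_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nzy <- d[1] * d[2]
  # linear-index offsets of the 26 neighbours
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  todo <- which(mask)
  lab <- 0L
  for (s in todo) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      fz <- (frontier - 1L) %% d[1] + 1L
      fy <- ((frontier - 1L) %/% d[1]) %% d[2] + 1L
      fx <- (frontier - 1L) %/% nzy + 1L
      nz <- rep(fz, each = 26L) + off[, 1]
      ny <- rep(fy, each = 26L) + off[, 2]
      nx <- rep(fx, each = 26L) + off[, 3]
      ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
        nx >= 1L & nx <= d[3]
      nb <- unique((nx[ok] - 1L) * nzy + (ny[ok] - 1L) * d[1] + nz[ok])
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

keep_largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components_26(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Segment the otolith at a CT-number threshold
#'
#' The segmented set is every ROI voxel with CT number at or above the
#' threshold, optionally reduced to its largest 26-connected component to
#' shed isolated noise voxels.
#'
#' @param vol a [ct_volume()].
#' @param roi logical search region.
#' @param threshold finite CT number.
#' @param keep_largest if `TRUE`, keep only the largest 26-connected
#'   component. Default `FALSE`.
#' @return logical mask on the volume's grid. An empty result is returned
#'   with a warning, not an error.
#' @export
segment_otolith <- function(vol, roi, threshold, keep_largest = FALSE) {
  check_same_grid(vol, roi, "roi")
  assert_scalar_number(threshold, "threshold")
  seg <- (roi != 0) & (vol$voxels >= threshold)
  if (!any(seg)) {
    warning("segmentation is empty at threshold ", signif(threshold, 6),
            call. = FALSE)
    return(seg)
  }
  if (keep_largest) seg <- keep_largest_component(seg)
  seg
}

#' Volume and mean CT number of a segmented region
#'
#' @param vol a [ct_volume()].
#' @param seg logical mask (typically from [segment_otolith()]).
#' @param meta optional [volume_meta()]; defaults to the volume's own.
#' @return list of class `morphometry_result` with `volume_voxels`,
#'   `volume_um3` (voxel count times voxel volume) and `mean_ct` (arithmetic
#'   mean of raw CT numbers over the mask; `NA` for an empty mask).
#' @export
quantify <- function(vol, seg, meta = vol$meta) {
  check_same_grid(vol, seg, "seg")
  n <- sum(seg != 0)
  structure(list(
    volume_voxels = n,
    volume_um3 = n * prod(meta$spacing_um),
    mean_ct = if (n > 0) mean(vol$voxels[seg != 0]) else NA_real_),
    class = "morphometry_result")
}

#' Striola edge volume from the dual threshold
#'
#' The edge set is the difference of two segmentations of the same ROI:
#' voxels detected at the relaxed threshold `0.9 T` but not at `T`. On a
#' noise-free phantom with a step boundary this set is empty; boundary blur
#' (the aged, gentle-slope phenotype) populates it.
#'
#' @param vol a [ct_volume()].
#' @param roi logical search region.
#' @param thr a `threshold_result` from [compute_threshold()].
#' @param keep_largest largest-component policy, applied identically to
#'   both segmentations.
#' @return list of class `edge_volume_result` with `edge_voxels`,
#'   `edge_volume_um3` and the logical `edge_mask`.
#' @export
striola_edge_volume <- function(vol, roi, thr, keep_largest = FALSE) {
  if (!inherits(thr, "threshold_result"))
    stop_input("`thr` must come from compute_threshold()")
  seg_lo <- suppressWarnings(
    segment_otolith(vol, roi, thr$edge_lower, keep_largest))
  seg_hi <- suppressWarnings(
    segment_otolith(vol, roi, thr$threshold, keep_largest))
  edge <- seg_lo & !seg_hi
  structure(list(edge_voxels = sum(edge),
                 edge_volume_um3 = sum(edge) * prod(vol$meta$spacing_um),
                 edge_mask = edge),
            class = "edge_volume_result")
}

#' Per-slice areas of a segmented mask
#'
#' Used for the cross-validation of CT areas against same-thickness
#' histological sections: slice thickness equals the voxel spacing along
#' the chosen axis, so summing `area * thickness` over slices recovers the
#' segmented volume.
#'
#' @param seg logical 3D mask.
#' @param meta a [volume_meta()].
#' @param axis slicing axis, one of `"z"` (default), `"y"`, `"x"`.
#' @return data.frame with `slice` (1-based index along the axis) and
#'   `area_um2` (in-slice voxel count times in-plane pixel area).
#' @export
slice_areas <- function(seg, meta, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  if (!is.array(seg) || length(dim(seg)) != 3L)
    stop_input("`seg` must be a 3D mask")
  ax <- match(axis, c("z", "y", "x"))
  counts <- apply(seg != 0, ax, sum)
  pix <- prod(meta$spacing_um[-ax])
  data.frame(slice = seq_along(counts), area_um2 = counts * pix)
}
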
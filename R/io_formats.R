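# External representations.
#
# Volumes: NIfTI (.nii / .nii.gz) is the primary format — voxel values are
# stored as doubles and the (z, y, x) spacing in micrometers travels in the
# header pixdim, so a write/read round trip is bit-identical. Multipage
# 32-bit-float TIFF is supported for interchange with slice-stack tooling;
# TIFF float samples must lie in [0, 1], so CT volumes are written with an
# affine rescale recorded in a JSON sidecar (<file>.json) that also carries
# the spacing, and are mapped back on read. Masks are written as 0/1
# volumes in either format.
#
# Traces, point sets, and cohort tables are plain CSV (one header row,
# UTF-8, '.' decimal), so every fixture is inspectable.

#' Read a 3D volume (NIfTI or multipage TIFF)
#'
#' @param path a `.nii`/`.nii.gz` file or a multipage `.tif`/`.tiff` file.
#'   For TIFF, a sidecar `<path>.json` (written by [write_volume()])
#'   supplies spacing and the value rescale; without one the values are
#'   taken as stored.
#' @return list with `volume` (a [ct_volume()], axis order z, y, x) and
#'   `meta` (a [volume_meta()]). Missing spacing falls back to 10 um
#'   isotropic with a warning.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_input("cannot read volume: no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop_input(sprintf("expected 3D data, got %dD: %s",
                         length(dim(arr)), path))
    sp <- RNifti::pixdim(img)
    # stored as (x, y, z); our convention is (z, y, x)
    arr <- aperm(arr, c(3, 2, 1))
    sp <- rev(sp)
    if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0) ||
        all(sp == 1)) {
      warning("no voxel spacing in header; defaulting to 10 um isotropic",
              call. = FALSE)
      sp <- c(10, 10, 10)
    }
    meta <- volume_meta(spacing_um = sp)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop_input(sprintf("expected a 3D stack, got %d page(s): %s",
                         length(pages), path))
    if (length(dim(pages[[1]])) != 2L)
      stop_input("TIFF pages must be single-channel 2D slices: ", path)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    arr <- aperm(arr, c(3, 1, 2))  # (z, y, x)
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      sc <- jsonlite::read_json(side, simplifyVector = TRUE)
      arr <- arr * sc$scale + sc$offset
      meta <- volume_meta(spacing_um = sc$spacing_um)
    } else {
      warning("no sidecar for TIFF stack; values as stored, spacing 10 um",
              call. = FALSE)
      meta <- volume_meta(spacing_um = c(10, 10, 10))
    }
  } else {
    stop_input("unsupported volume format (use .nii, .nii.gz, .tif): ", path)
  }
  list(volume = ct_volume(arr, meta), meta = meta)
}

#' Write a 3D volume (NIfTI or multipage TIFF)
#'
#' @param vol a [ct_volume()] or a plain 3D array (axis order z, y, x).
#' @param path destination; format chosen by extension.
#' @param meta a [volume_meta()] (defaults to the volume's own).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, meta = NULL) {
  if (inherits(vol, "ct_volume")) {
    if (is.null(meta)) meta <- vol$meta
    arr <- vol$voxels
  } else {
    arr <- vol * 1  # coerce logical masks to numeric
    if (is.null(meta)) meta <- volume_meta()
  }
  if (length(dim(arr)) != 3L) stop_input("volume must be 3D")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))   # store as (x, y, z)
    RNifti::pixdim(img) <- rev(meta$spacing_um)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(arr)
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    offset <- rng[1]
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(k) (arr[k, , ] - offset) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(scale = scale, offset = offset,
                              spacing_um = meta$spacing_um),
                         paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop_input("unsupported volume format (use .nii, .nii.gz, .tif): ", path)
  }
  invisible(path)
}

#' Read a uniformly sampled trace table from CSV
#'
#' @param path CSV with a header row: a `t` (seconds) column plus at least
#'   one channel column.
#' @param tol_s tolerance on sample-interval uniformity (default 1e-6 s).
#' @return data.frame with the file's columns; attribute `rate_hz` holds
#'   the inferred sampling rate.
#' @export
read_trace <- function(path, tol_s = 1e-6) {
  if (!file.exists(path))
    stop_input("cannot read trace: no such file: ", path)
  d <- utils::read.csv(path)
  if (!"t" %in% names(d))
    stop_input("trace CSV needs a `t` column (seconds): ", path)
  if (ncol(d) < 2L)
    stop_input("trace CSV needs at least one channel besides `t`: ", path)
  attr(d, "rate_hz") <- check_uniform_time(d$t, tol_s)
  if (all(c("position_mm", "velocity_mm_s") %in% names(d)))
    class(d) <- c("sled_trace", "data.frame")
  else if ("eye_y_deg" %in% names(d))
    class(d) <- c("eye_trace", "data.frame")
  d
}

#' Write a trace table to CSV
#'
#' @param trace data.frame with a `t` column.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a layer tracing from CSV
#'
#' @param path CSV with columns `set_label` (`"les"` / `"base"`), `x_um`,
#'   `y_um`.
#' @return a `layer_trace` list with `les_points` and `base_points`.
#' @export
read_layer_points <- function(path) {
  if (!file.exists(path))
    stop_input("cannot read layer points: no such file: ", path)
  d <- utils::read.csv(path)
  need <- c("set_label", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop_input("layer-point CSV needs columns: ", paste(need, collapse = ", "))
  if (!all(d$set_label %in% c("les", "base")))
    stop_input("set_label must be \"les\" or \"base\"")
  pick <- function(lbl) as.matrix(d[d$set_label == lbl, c("x_um", "y_um")])
  structure(list(les_points = pick("les"), base_points = pick("base")),
            class = "layer_trace")
}

#' Write a layer tracing to CSV
#'
#' @param trace a `layer_trace`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_layer_points <- function(trace, path) {
  d <- rbind(
    data.frame(set_label = "les", x_um = trace$les_points[, 1],
               y_um = trace$les_points[, 2]),
    data.frame(set_label = "base", x_um = trace$base_points[, 1],
               y_um = trace$base_points[, 2]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-ear cohort table from CSV
#'
#' @param path CSV with columns `age_group`, `sex`, `measurement`, `value`
#'   (plus any identifiers).
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_input("cannot read cohort: no such file: ", path)
  d <- utils::read.csv(path)
  need <- c("age_group", "sex", "measurement", "value")
  if (!all(need %in% names(d)))
    stop_input("cohort CSV needs columns: ", paste(need, collapse = ", "))
  d
}
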
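# Otolith layer angle from traced 2D point sets.
#
# The angle between the lateral-extrastriola otoconial surface and the
# basal plane of the striola is a morphological marker of striola
# integrity: 90 degrees means a sharply delimited striola, 0 means the
# boundary has collapsed. Each traced point set is reduced to a direction
# by total least squares (orthogonal regression), which — unlike ordinary
# regression — is invariant to the choice of image axes.

#' Fit a line direction to a 2D point set by total least squares
#'
#' @param points numeric matrix (n x 2) of coordinates in micrometers,
#'   n >= 2, not all coincident.
#' @return list with `direction` (unit 2-vector, sign-normalized so its
#'   first nonzero component is positive), `centroid`, and `rms_um` (root
#'   mean square orthogonal residual).
#' @export
fit_direction <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 2L)
    stop_input("`points` must be an n x 2 numeric matrix with n >= 2")
  if (any(!is.finite(points))) stop_input("`points` must be finite")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  if (all(abs(x) < 1e-12))
    stop_input("degenerate input: all points coincide")
  sv <- svd(x)
  d <- sv$v[, 1]
  nz <- which(abs(d) > 1e-12)[1]
  if (d[nz] < 0) d <- -d
  # orthogonal residuals are the projections on the minor axis
  res <- x %*% sv$v[, 2]
  list(direction = as.numeric(d), centroid = as.numeric(ctr),
       rms_um = sqrt(mean(res^2)))
}

#' Otolith layer angle between LES and striola base tracings
#'
#' Fits a total-least-squares direction to each point set and returns the
#' acute angle between them, folded into \[0, 90\] degrees via the absolute
#' cosine (a traced line has no preferred orientation).
#'
#' @param trace a `layer_trace` (see [gen_layer_points()]) or any list with
#'   `les_points` and `base_points` n x 2 matrices.
#' @return list of class `angle_result` with `angle_deg` in \[0, 90\] and
#'   `fit_rms_um`, a named vector of per-line residuals.
#' @export
layer_angle <- function(trace) {
  if (is.null(trace$les_points) || is.null(trace$base_points))
    stop_input("`trace` must carry `les_points` and `base_points`")
  f1 <- fit_direction(trace$les_points)
  f2 <- fit_direction(trace$base_points)
  cosang <- min(1, abs(sum(f1$direction * f2$direction)))
  structure(list(angle_deg = acos(cosang) * 180 / pi,
                 fit_rms_um = c(les = f1$rms_um, base = f2$rms_um)),
            class = "angle_result")
}
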
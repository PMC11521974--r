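# Synthetic electron-microscopy layer tracings.
#
# The otolith layer angle is measured between two traced lines on a 2D
# micrograph: the lateral-extrastriola (LES) otoconial surface and the
# basal plane of the striola. The generator lays points along two lines
# meeting at a prescribed angle and jitters them isotropically, which is
# the error model for manual point placement on a micrograph.

#' Generate a synthetic layer tracing at a known angle
#'
#' @param angle_deg true angle between the two lines, in \[0, 90\] degrees.
#' @param n_points points per line (>= 2).
#' @param noise_um isotropic Gaussian jitter s.d. applied to both
#'   coordinates, micrometers.
#' @param seed integer seed, required whenever `noise_um > 0`.
#' @param length_um traced length of each line segment (default 100 um,
#'   a typical extent of the striola region on a micrograph).
#' @return list of class `layer_trace` with `les_points` and `base_points`,
#'   each an `n_points x 2` matrix of (x, y) in micrometers, plus the
#'   generating `angle_deg`.
#' @export
gen_layer_points <- function(angle_deg, n_points = 50L, noise_um = 0,
                             seed = NULL, length_um = 100) {
  assert_scalar_number(angle_deg, "angle_deg")
  if (angle_deg < 0 || angle_deg > 90)
    stop_input("`angle_deg` must lie in [0, 90]")
  if (!is.numeric(n_points) || n_points < 2)
    stop_input("`n_points` must be >= 2")
  assert_scalar_number(noise_um, "noise_um", nonneg = TRUE)
  assert_scalar_number(length_um, "length_um", positive = TRUE)
  if (noise_um > 0) seed <- assert_seed(seed)
  s <- seq(-length_um / 2, length_um / 2, length.out = n_points)
  th <- angle_deg * pi / 180
  base <- cbind(x_um = s, y_um = rep(0, n_points))
  les <- cbind(x_um = s * cos(th), y_um = s * sin(th))
  if (noise_um > 0) {
    set.seed(seed)
    base <- base + matrix(stats::rnorm(2 * n_points, sd = noise_um),
                          ncol = 2)
    les <- les + matrix(stats::rnorm(2 * n_points, sd = noise_um), ncol = 2)
  }
  structure(list(les_points = les, base_points = base,
                 angle_deg = angle_deg),
            class = "layer_trace")
}
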
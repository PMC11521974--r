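# Synthetic micro-CT otolith phantom.
#
# The phantom is an ellipsoidal high-density body (the otoconial mass of a
# utricle or saccule) embedded in a uniform soft-tissue background, with a
# planar low-density channel through the center standing in for the striola,
# the thin central band of the macula. Boundary sharpness is controlled by a
# Gaussian blur of the noiseless density field: a steep CT-number slope at
# the otolith boundary corresponds to a young-type organ, a gentle slope to
# an aged one, which is what the dual-threshold edge statistic measures.

#' Parameters of the synthetic otolith phantom
#'
#' @param grid integer triple, voxel counts along (z, y, x).
#' @param spacing_um positive triple, voxel size in micrometers along
#'   (z, y, x). Default 5 um isotropic.
#' @param semi_axes_um positive triple, ellipsoid semi-axes in micrometers
#'   along (z, y, x).
#' @param mu_otolith CT number inside the otoconial body.
#' @param mu_background CT number of the surrounding tissue/fluid; must be
#'   below `mu_otolith`.
#' @param striola_width_um full width (um) of the planar striola channel
#'   through the ellipsoid center; 0 disables it.
#' @param striola_depth fraction in \[0, 1\]: density inside the channel is
#'   reduced by `striola_depth * (mu_otolith - mu_background)`. The default
#'   0.8 places the striola distinctly below the dual-threshold edge band so
#'   it reads as the low-density central area seen in reconstructed organs.
#' @param edge_blur_um standard deviation (um) of the Gaussian applied to
#'   the noiseless density field; this is the aging knob for the edge
#'   statistic. Default 0 (steep, young-type boundary).
#' @param noise_sd standard deviation of i.i.d. Gaussian CT-number noise
#'   added after blurring.
#' @param roi_dilate_um how far (um) the otolith ROI extends beyond the
#'   ellipsoid surface, emulating a manually drawn ROI that includes some
#'   surrounding fluid.
#' @param seed integer seed; required, there is no default.
#' @return a validated parameter list of class `phantom_params`.
#' @seealso [gen_ct_phantom()]
#' @export
phantom_params <- function(grid = c(64L, 64L, 64L),
                           spacing_um = c(5, 5, 5),
                           semi_axes_um = c(40, 60, 100),
                           mu_otolith = 200,
                           mu_background = 50,
                           striola_width_um = 16,
                           striola_depth = 0.8,
                           edge_blur_um = 0,
                           noise_sd = 5,
                           roi_dilate_um = 10,
                           seed = NULL) {
  assert_triple(grid, "grid", positive = TRUE)
  assert_triple(spacing_um, "spacing_um", positive = TRUE)
  assert_triple(semi_axes_um, "semi_axes_um", positive = TRUE)
  assert_scalar_number(mu_otolith, "mu_otolith")
  assert_scalar_number(mu_background, "mu_background")
  assert_scalar_number(striola_width_um, "striola_width_um", nonneg = TRUE)
  assert_scalar_number(striola_depth, "striola_depth", nonneg = TRUE)
  assert_scalar_number(edge_blur_um, "edge_blur_um", nonneg = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_number(roi_dilate_um, "roi_dilate_um", nonneg = TRUE)
  if (mu_otolith <= mu_background)
    stop_input("`mu_otolith` must exceed `mu_background`")
  if (striola_depth > 1)
    stop_input("`striola_depth` must lie in [0, 1]")
  extent <- (grid - 1) * spacing_um / 2
  if (any(semi_axes_um + roi_dilate_um >= extent))
    stop_input(sprintf(
      "ellipsoid plus ROI margin exceeds the grid: semi-axes+dilation (%s) um vs half-extent (%s) um",
      paste(semi_axes_um + roi_dilate_um, collapse = ", "),
      paste(round(extent, 1), collapse = ", ")))
  p <- list(grid = as.integer(grid), spacing_um = as.numeric(spacing_um),
            semi_axes_um = as.numeric(semi_axes_um),
            mu_otolith = mu_otolith, mu_background = mu_background,
            striola_width_um = striola_width_um,
            striola_depth = striola_depth,
            edge_blur_um = edge_blur_um, noise_sd = noise_sd,
            roi_dilate_um = roi_dilate_um,
            seed = if (noise_sd > 0) assert_seed(seed) else
              if (is.null(seed)) NA_integer_ else assert_seed(seed))
  class(p) <- "phantom_params"
  p
}

# Squared normalized ellipsoid radius at each voxel center, for semi-axes
# scaled by `scale` and offset by `margin_um`. Physical coordinate of voxel
# i (1-based) along an axis is (i - 1) * spacing.
ellipsoid_field <- function(grid, spacing_um, semi_axes_um, margin_um = 0) {
  ctr <- (grid - 1) / 2 * spacing_um
  ax <- semi_axes_um + margin_um
  dz <- (((seq_len(grid[1]) - 1) * spacing_um[1] - ctr[1]) / ax[1])^2
  dy <- (((seq_len(grid[2]) - 1) * spacing_um[2] - ctr[2]) / ax[2])^2
  dx <- (((seq_len(grid[3]) - 1) * spacing_um[3] - ctr[3]) / ax[3])^2
  outer(outer(dz, dy, `+`), dx, `+`)
}

# Separable 3D Gaussian smoothing (sigma in voxels per axis), edge-replicated.
gaussian_smooth_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    # bring axis `ax` first, flatten to a matrix, filter column-wise
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(dm[1], r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    m <- f[(r + 1L):(r + dm[1]), , drop = FALSE]
    dim(m) <- dm
    a <- aperm(m, order(perm))
  }
  a
}

#' Generate a synthetic otolith CT phantom
#'
#' Builds the noiseless density field (background, ellipsoidal otolith,
#' planar striola channel), applies Gaussian boundary blur, adds voxel
#' noise, and derives the two regions of interest the thresholding step
#' needs: an otolith ROI (the ellipsoid dilated by `roi_dilate_um`, so it
#' deliberately contains some background, as a hand-drawn ROI would) and a
#' disjoint surrounding-tissue ROI (a background shell further out).
#'
#' Ground truth is recorded from the pre-blur, pre-noise field.
#'
#' @param p a [phantom_params()] object.
#' @return a list with elements
#'   \describe{
#'     \item{volume}{`ct_volume`: the noisy CT volume.}
#'     \item{rois}{`roi_pair`: `otolith_roi` and `tissue_roi` logical arrays.}
#'     \item{truth}{list: `otolith_mask` (ellipsoid), `striola_mask`,
#'       `supra_mask` (otolith minus striola, i.e. the voxels whose true
#'       density is `mu_otolith`), the corresponding voxel counts and
#'       volumes in um^3, and `analytic_volume_um3` = (4/3) pi a b c.}
#'   }
#' @examples
#' ph <- gen_ct_phantom(phantom_params(grid = c(32, 32, 32),
#'                                     semi_axes_um = c(25, 30, 40),
#'                                     noise_sd = 0))
#' ph$truth$volume_um3 / ph$truth$analytic_volume_um3
#' @export
gen_ct_phantom <- function(p) {
  if (!inherits(p, "phantom_params")) p <- do.call(phantom_params, p)
  vx <- prod(p$spacing_um)

  r2 <- ellipsoid_field(p$grid, p$spacing_um, p$semi_axes_um)
  oto <- r2 <= 1

  # planar channel through the center, normal along x (the long axis by
  # default), clipped to the ellipsoid
  ctr_x <- (p$grid[3] - 1) / 2 * p$spacing_um[3]
  x <- (seq_len(p$grid[3]) - 1) * p$spacing_um[3]
  in_slab <- abs(x - ctr_x) <= p$striola_width_um / 2
  slab <- array(rep(in_slab, each = p$grid[1] * p$grid[2]), dim = p$grid)
  striola <- oto & slab & (p$striola_width_um > 0) & (p$striola_depth > 0)

  field <- array(p$mu_background, dim = p$grid)
  field[oto] <- p$mu_otolith
  field[striola] <- p$mu_otolith -
    p$striola_depth * (p$mu_otolith - p$mu_background)

  truth <- list(
    otolith_mask = oto,
    striola_mask = striola,
    supra_mask = oto & !striola,
    n_voxels = sum(oto),
    volume_um3 = sum(oto) * vx,
    supra_volume_um3 = sum(oto & !striola) * vx,
    analytic_volume_um3 = 4 / 3 * pi * prod(p$semi_axes_um),
    mu_otolith = p$mu_otolith,
    mu_background = p$mu_background)

  if (p$edge_blur_um > 0)
    field <- gaussian_smooth_3d(field, p$edge_blur_um / p$spacing_um)
  if (p$noise_sd > 0) {
    set.seed(p$seed)
    field <- field + array(stats::rnorm(length(field), sd = p$noise_sd),
                           dim = p$grid)
  }

  roi_oto <- ellipsoid_field(p$grid, p$spacing_um, p$semi_axes_um,
                             margin_um = p$roi_dilate_um) <= 1
  shell_in <- ellipsoid_field(p$grid, p$spacing_um, p$semi_axes_um,
                              margin_um = p$roi_dilate_um +
                                max(p$spacing_um)) <= 1
  shell_out <- ellipsoid_field(p$grid, p$spacing_um, p$semi_axes_um,
                               margin_um = p$roi_dilate_um +
                                 4 * max(p$spacing_um)) <= 1
  roi_tis <- shell_out & !shell_in

  meta <- volume_meta(spacing_um = p$spacing_um)
  list(volume = ct_volume(field, meta),
       rois = roi_pair(roi_oto, roi_tis),
       truth = truth,
       params = p)
}
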
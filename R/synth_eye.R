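# Synthetic axis-angle eye traces for the linear vestibulo-ocular reflex.
#
# During linear translation in the dark, the dominant mouse eye movement is
# a disconjugate vertical shift whose waveform follows the head's linear
# ACCELERATION, not its position. The generator therefore drives the
# vertical (Y) axis-angle component linearly from the sled acceleration:
#
#   eye_y(t) = gain_deg_per_G * a(t)/g + drift * t + noise,
#
# with positive acceleration producing a positive (upward) vertical shift of
# the left eye. The torsional (X) and horizontal (Z) components are
# noise-only by default. An optional pure transport delay is provided; the
# default model is lag-free.

#' Eye-response model parameters
#'
#' @param gain_deg_per_G vertical response amplitude per unit linear
#'   acceleration, deg/G. This is the quantity the otolith function index
#'   estimates (peak response = `gain * a_max/g`).
#' @param noise_sd_deg standard deviation of i.i.d. Gaussian measurement
#'   noise on every axis, deg.
#' @param drift_deg_per_s linear baseline drift of the vertical component.
#' @param lag_s optional pure response delay, s (default 0: lag-free).
#' @param seed integer seed, required whenever `noise_sd_deg > 0`.
#' @return a validated list of class `eye_model_params`.
#' @export
eye_model_params <- function(gain_deg_per_G = 2, noise_sd_deg = 0.05,
                             drift_deg_per_s = 0, lag_s = 0, seed = NULL) {
  assert_scalar_number(gain_deg_per_G, "gain_deg_per_G")
  assert_scalar_number(noise_sd_deg, "noise_sd_deg", nonneg = TRUE)
  assert_scalar_number(drift_deg_per_s, "drift_deg_per_s")
  assert_scalar_number(lag_s, "lag_s", nonneg = TRUE)
  structure(list(gain_deg_per_G = gain_deg_per_G,
                 noise_sd_deg = noise_sd_deg,
                 drift_deg_per_s = drift_deg_per_s, lag_s = lag_s,
                 seed = if (noise_sd_deg > 0) assert_seed(seed) else
                   if (is.null(seed)) NA_integer_ else assert_seed(seed)),
            class = "eye_model_params")
}

#' Generate a left-eye axis-angle trace from a sled trace
#'
#' @param sled a `sled_trace` (from [gen_sled_trace()] or
#'   [derive_kinematics()]) carrying an acceleration channel.
#' @param p an [eye_model_params()] object.
#' @return data.frame of class `eye_trace` with columns `t`, `eye_x_deg`,
#'   `eye_y_deg`, `eye_z_deg`; attribute `rate_hz`.
#' @export
gen_eye_trace <- function(sled, p) {
  if (!inherits(p, "eye_model_params")) p <- do.call(eye_model_params, p)
  if (is.null(sled$acceleration_mm_s2))
    stop_input("`sled` has no acceleration channel; derive kinematics first")
  fs <- attr(sled, "rate_hz")
  if (is.null(fs)) fs <- check_uniform_time(sled$t)
  a_G <- sled$acceleration_mm_s2 / 1000 / G_MS2
  if (p$lag_s > 0) {
    k <- round(p$lag_s * fs)
    a_G <- c(rep(a_G[1], k), a_G[seq_len(length(a_G) - k)])
  }
  n <- length(a_G)
  y <- p$gain_deg_per_G * a_G + p$drift_deg_per_s * sled$t
  x <- z <- numeric(n)
  if (p$noise_sd_deg > 0) {
    set.seed(p$seed)
    y <- y + stats::rnorm(n, sd = p$noise_sd_deg)
    x <- x + stats::rnorm(n, sd = p$noise_sd_deg)
    z <- z + stats::rnorm(n, sd = p$noise_sd_deg)
  }
  out <- data.frame(t = sled$t, eye_x_deg = x, eye_y_deg = y, eye_z_deg = z)
  attr(out, "rate_hz") <- fs
  class(out) <- c("eye_trace", "data.frame")
  out
}
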
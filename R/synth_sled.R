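# Trapezoidal-velocity sled motion profile.
#
# The sled runs between two ends 1.8 m apart, dwelling 0.3 s at each end,
# and reciprocates five times. Each one-way leg is a trapezoidal-velocity
# move: accelerate at a_max to v_max, cruise, decelerate at a_max; both
# the acceleration and speed bounds are attained exactly. The two stimulus
# levels of the study are 1.3 G with 3.25 m/s and 0.7 G with 3.06 m/s.

#' Sled motion-profile parameters
#'
#' @param a_max maximum acceleration magnitude, m/s^2. Default 1.3 G.
#' @param v_max maximum speed, m/s. Default 3.25.
#' @param distance_m one-way travel, m. Default 1.8.
#' @param dwell_s stationary time at each end, s. Default 0.3.
#' @param n_round_trips number of full reciprocations. Default 5.
#' @param rate_hz sampling rate, Hz. Default 240.
#' @param orientation `"lateral"` (interaural stimulation, utricle) or
#'   `"longitudinal"` (cephalonasal, saccule).
#' @return a validated list of class `sled_params`.
#' @export
sled_params <- function(a_max = 1.3 * G_MS2, v_max = 3.25, distance_m = 1.8,
                        dwell_s = 0.3, n_round_trips = 5L, rate_hz = 240,
                        orientation = c("lateral", "longitudinal")) {
  orientation <- match.arg(orientation)
  assert_scalar_number(a_max, "a_max", positive = TRUE)
  assert_scalar_number(v_max, "v_max", positive = TRUE)
  assert_scalar_number(distance_m, "distance_m", positive = TRUE)
  assert_scalar_number(dwell_s, "dwell_s", positive = TRUE)
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (n_round_trips < 1) stop_input("`n_round_trips` must be >= 1")
  if (v_max^2 / a_max > distance_m)
    stop_input(sprintf(
      "infeasible kinematics: reaching and leaving v_max = %g m/s at a_max = %g m/s^2 needs %.3g m but the travel is %g m",
      v_max, a_max, v_max^2 / a_max, distance_m))
  structure(list(a_max = a_max, v_max = v_max, distance_m = distance_m,
                 dwell_s = dwell_s, n_round_trips = as.integer(n_round_trips),
                 rate_hz = rate_hz, orientation = orientation),
            class = "sled_params")
}

# Analytic one-way trapezoid evaluated at local times (vectors of position
# m, velocity m/s, acceleration m/s^2).
trapezoid_eval <- function(t, a, v, D) {
  t_a <- v / a                      # ramp time
  t_c <- (D - v^2 / a) / v          # cruise time
  t_tot <- 2 * t_a + t_c
  pos <- vel <- acc <- numeric(length(t))
  ph1 <- t < t_a
  ph2 <- t >= t_a & t < t_a + t_c
  ph3 <- t >= t_a + t_c & t < t_tot
  ph4 <- t >= t_tot
  pos[ph1] <- a * t[ph1]^2 / 2
  vel[ph1] <- a * t[ph1]
  acc[ph1] <- a
  pos[ph2] <- v^2 / (2 * a) + v * (t[ph2] - t_a)
  vel[ph2] <- v
  td <- t[ph3] - t_a - t_c
  pos[ph3] <- D - v^2 / (2 * a) + v * td - a * td^2 / 2
  vel[ph3] <- v - a * td
  acc[ph3] <- -a
  pos[ph4] <- D
  list(pos = pos, vel = vel, acc = acc, t_total = t_tot)
}

#' Generate a sled position/kinematics trace
#'
#' Concatenates, at the sampling rate, an initial dwell, then alternating
#' one-way trapezoidal legs and end dwells for `n_round_trips` round trips.
#' Dwells span exactly `round(dwell_s * rate_hz)` zero-velocity samples.
#' Velocity and acceleration channels are the analytic profile sampled at
#' the same instants, so the stated kinematic bounds are attained exactly.
#'
#' @param p a [sled_params()] object.
#' @return a data.frame of class `sled_trace` with columns `t` (s),
#'   `position_mm`, `velocity_mm_s`, `acceleration_mm_s2`, and attributes
#'   `rate_hz`, `orientation`, `params`.
#' @examples
#' tr <- gen_sled_trace(sled_params())
#' max(abs(tr$acceleration_mm_s2)) / 1000 / 9.81  # 1.3 G
#' @export
gen_sled_trace <- function(p) {
  if (!inherits(p, "sled_params")) p <- do.call(sled_params, p)
  fs <- p$rate_hz
  dt <- 1 / fs
  n_dwell <- round(p$dwell_s * fs)
  leg <- trapezoid_eval(0, p$a_max, p$v_max, p$distance_m)
  n_leg <- floor(leg$t_total * fs)      # last in-leg sample strictly before arrival
  if (n_leg * dt >= leg$t_total - 1e-12) n_leg <- n_leg - 1L
  t_loc <- (1:n_leg) * dt
  fwd <- trapezoid_eval(t_loc, p$a_max, p$v_max, p$distance_m)

  pos <- rep(0, n_dwell)
  vel <- rep(0, n_dwell)
  acc <- rep(0, n_dwell)
  at_far <- FALSE
  for (i in seq_len(2L * p$n_round_trips)) {
    if (!at_far) {
      pos <- c(pos, fwd$pos, rep(p$distance_m, n_dwell))
    } else {
      pos <- c(pos, p$distance_m - fwd$pos, rep(0, n_dwell))
    }
    vel <- c(vel, (if (at_far) -1 else 1) * fwd$vel, rep(0, n_dwell))
    acc <- c(acc, (if (at_far) -1 else 1) * fwd$acc, rep(0, n_dwell))
    at_far <- !at_far
  }
  n <- length(pos)
  out <- data.frame(t = (seq_len(n) - 1L) * dt,
                    position_mm = pos * 1000,
                    velocity_mm_s = vel * 1000,
                    acceleration_mm_s2 = acc * 1000)
  attr(out, "rate_hz") <- fs
  attr(out, "orientation") <- p$orientation
  attr(out, "params") <- p
  class(out) <- c("sled_trace", "data.frame")
  out
}
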
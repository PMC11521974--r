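# Linear vestibulo-ocular reflex analysis.
#
# From a sled marker-position trace the module derives velocity and
# acceleration, segments the recording into stimulation cycles (one cycle =
# one round trip between end dwells), and computes the otolith function
# index from the vertical component of the left eye's axis-angle trace:
#
#   index per cycle = (max positive shift - max negative shift) / 2
#
# relative to the rest baseline, aggregated as the mean of the three
# largest of the five cycles. The eye waveform tracks the sled's linear
# acceleration, so for a response gain g (deg/G) and peak acceleration
# a_max the noiseless index equals g * a_max / g0.

#' Derive sled kinematics from a position trace
#'
#' Velocity and acceleration by centered finite differences (one-sided at
#' the endpoints) after zero-phase moving-average smoothing of the
#' position; a window of 1 disables smoothing.
#'
#' @param position_mm numeric vector of marker positions, mm (>= 3 samples).
#' @param rate_hz sampling rate, Hz.
#' @param smooth_window odd moving-average window in samples. Default 5
#'   (about 21 ms at 240 Hz), enough to tame marker-digitization noise
#'   without flattening the 0.25 s acceleration plateaus.
#' @return data.frame of class `sled_trace` with `t`, `position_mm`,
#'   `velocity_mm_s`, `acceleration_mm_s2`; attribute `rate_hz`.
#' @export
derive_kinematics <- function(position_mm, rate_hz, smooth_window = 5L) {
  if (length(position_mm) < 3L)
    stop_input("need at least 3 samples to differentiate")
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  dt <- 1 / rate_hz
  p <- smooth_ma(position_mm, smooth_window)
  cdiff <- function(x) {
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d
  }
  v <- cdiff(p)
  a <- cdiff(v)
  out <- data.frame(t = (seq_along(p) - 1L) * dt, position_mm = position_mm,
                    velocity_mm_s = v, acceleration_mm_s2 = a)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("sled_trace", "data.frame")
  out
}

#' Segment a sled trace into stimulation cycles
#'
#' Dwells are maximal runs with `|velocity| <= v_dwell_mm_s` lasting at
#' least `min_dwell_s`. A cycle — one round trip — runs from the start of
#' motion after an even-numbered dwell to the start of motion after the
#' dwell two later (or to the end of the trace for the final cycle). All
#' complete cycles are returned; the study protocol yields five.
#'
#' @param sled a `sled_trace` with a velocity channel.
#' @param v_dwell_mm_s speed below which the sled counts as stationary.
#'   Default 20 mm/s.
#' @param min_dwell_s minimum dwell duration. Default 0.25 s, safely under
#'   the protocol's 0.3 s end dwells.
#' @return list of class `cycle_set`: `cycles` (data.frame `start`, `end`,
#'   sample indices), `dwells` (data.frame `start`, `end`), `rate_hz`.
#' @export
segment_cycles <- function(sled, v_dwell_mm_s = 20, min_dwell_s = 0.25) {
  if (is.null(sled$velocity_mm_s))
    stop_input("`sled` has no velocity channel; derive kinematics first")
  fs <- attr(sled, "rate_hz")
  if (is.null(fs)) fs <- check_uniform_time(sled$t)
  still <- abs(sled$velocity_mm_s) <= v_dwell_mm_s
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dwell_s * fs
  dwells <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(dwells) < 3L)
    stop_input(sprintf(
      "cannot segment cycles: found %d dwell(s) >= %g s; a complete round trip needs 3",
      nrow(dwells), min_dwell_s))
  n <- length(still)
  motion_start <- ifelse(dwells$end < n, dwells$end + 1L, n)
  first <- seq(1L, nrow(dwells) - 2L, by = 2L)
  cycles <- data.frame(start = motion_start[first],
                       end = ifelse(first + 2L == nrow(dwells),
                                    n, motion_start[first + 2L] - 1L))
  structure(list(cycles = cycles, dwells = dwells, rate_hz = fs),
            class = "cycle_set")
}

#' Half-range eye shift within one cycle
#'
#' `(max(y - baseline) - min(y - baseline)) / 2` over the cycle window —
#' half the peak-to-peak excursion, invariant to any additive offset and to
#' time reversal of the window.
#'
#' @param y numeric vector, vertical eye component (deg).
#' @param window integer vector of sample indices (or a list/row with
#'   `start` and `end`).
#' @param baseline_deg rest-position baseline to subtract (cancels
#'   algebraically; kept for reporting symmetry).
#' @return nonnegative scalar, degrees.
#' @export
cycle_index <- function(y, window, baseline_deg = 0) {
  if (is.list(window) || is.data.frame(window))
    window <- seq(window$start, window$end)
  if (length(window) == 0L) stop_input("empty cycle window")
  if (min(window) < 1L || max(window) > length(y))
    stop_input("cycle window exceeds the trace")
  s <- y[window] - baseline_deg
  (max(s) - min(s)) / 2
}

#' Otolith function index from an eye trace and segmented cycles
#'
#' The baseline is the mean vertical component over all detected dwell
#' samples (the eye at rest). The vertical trace is smoothed with a
#' zero-phase moving average before peak extraction; per-cycle half-ranges
#' are then aggregated as the mean of the three largest values.
#'
#' @param eye an `eye_trace` (column `eye_y_deg`).
#' @param cycles a `cycle_set` from [segment_cycles()] with >= 3 cycles.
#' @param smooth_window odd smoothing window in samples for the vertical
#'   component before peak extraction. Default 41 (about 0.17 s at 240 Hz):
#'   short enough to preserve the >= 0.25 s constant-acceleration plateaus
#'   that carry the peak response, long enough to keep sample noise from
#'   inflating the extrema.
#' @return list of class `index_result`: `per_cycle` (deg), `index` (deg),
#'   `baseline_deg`, `n_cycles`.
#' @export
otolith_function_index <- function(eye, cycles, smooth_window = 41L) {
  if (is.null(eye$eye_y_deg)) stop_input("`eye` has no `eye_y_deg` column")
  if (!inherits(cycles, "cycle_set"))
    stop_input("`cycles` must come from segment_cycles()")
  nc <- nrow(cycles$cycles)
  if (nc < 3L)
    stop_input(sprintf("need at least 3 cycles, got %d", nc))
  dwell_idx <- unlist(mapply(seq, cycles$dwells$start, cycles$dwells$end,
                             SIMPLIFY = FALSE))
  y <- smooth_ma(eye$eye_y_deg, smooth_window)
  baseline <- mean(y[dwell_idx])
  per_cycle <- vapply(seq_len(nc), function(k)
    cycle_index(y, cycles$cycles[k, ], baseline), numeric(1))
  top3 <- sort(per_cycle, decreasing = TRUE)[1:3]
  structure(list(per_cycle = per_cycle, index = mean(top3),
                 baseline_deg = baseline, n_cycles = nc),
            class = "index_result")
}

#' Label an LVOR run with the organ it stimulates
#'
#' Lateral (interaural) translation stimulates the utricle; longitudinal
#' (cephalonasal) translation stimulates the saccule.
#'
#' @param orientation `"lateral"` or `"longitudinal"`.
#' @param accel_level `"1.3G"`, `"0.7G"`, or the numbers 1.3 / 0.7.
#' @return one-row data.frame with `orientation`, `accel_level`, `organ`,
#'   and the combined `tag` (e.g. `"utricle_1.3G"`).
#' @export
orient_run <- function(orientation, accel_level) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      !orientation %in% c("lateral", "longitudinal"))
    stop_input("`orientation` must be \"lateral\" or \"longitudinal\"")
  if (is.numeric(accel_level)) accel_level <- sprintf("%.1fG", accel_level)
  if (!accel_level %in% c("1.3G", "0.7G"))
    stop_input("`accel_level` must be \"1.3G\" or \"0.7G\"")
  organ <- if (orientation == "lateral") "utricle" else "saccule"
  data.frame(orientation = orientation, accel_level = accel_level,
             organ = organ, tag = paste0(organ, "_", accel_level))
}
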
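# Internal helpers shared across modules.

# Standard gravity used to convert between m/s^2 and G throughout the
# package (sled programming and eye-model gain are both specified in G).
G_MS2 <- 9.81

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_input(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_input(sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}

assert_triple <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop_input(sprintf("`%s` must be a numeric triple", name))
  if (positive && any(x <= 0))
    stop_input(sprintf("all elements of `%s` must be > 0", name))
  invisible(x)
}

assert_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed))
    stop_input("an explicit integer `seed` is required for randomized generators")
  invisible(as.integer(seed))
}

#' Zero-phase moving-average smoothing
#'
#' Symmetric (hence zero-phase) moving average with edge replication, used
#' before numerical differentiation of sled positions and before peak
#' extraction on eye traces. A window of 1 returns the input unchanged.
#'
#' @param x numeric vector.
#' @param window odd positive integer window length in samples.
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
smooth_ma <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window) || window %% 2 == 0)
    stop_input("`window` must be an odd positive integer")
  if (window == 1L) return(x)
  r <- (window - 1L) / 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  out <- stats::filter(xp, rep(1 / window, window), sides = 2)
  as.numeric(out[(r + 1L):(r + length(x))])
}

# Uniform-sampling check used by trace readers and constructors.
check_uniform_time <- function(t, tol_s = 1e-6) {
  if (length(t) < 2L)
    stop_input("a trace needs at least 2 samples to define a sampling rate")
  dt <- diff(t)
  if (any(dt <= 0))
    stop_input("time column must be strictly increasing")
  if (max(dt) - min(dt) > tol_s)
    stop_input(sprintf(
      "non-uniform time base: sample intervals vary by %.3g s (> %.1g s tolerance)",
      max(dt) - min(dt), tol_s))
  1 / mean(dt)
}
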
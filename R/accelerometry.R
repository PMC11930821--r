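#' Min-max scale a signal to [0, 1]
#'
#' `(x - min) / (max - min)`. Accelerometer placement introduces per-axis
#' gains and offsets with no physiological meaning; min-max scaling removes
#' them (the whole downstream pipeline is invariant to `a*x + b`, `a > 0`).
#' A constant axis maps to all zeros with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Scaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples to min-max scale", call. = FALSE)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant axis: min-max scaling undefined, returning zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Three-axis accelerometer trace
#'
#' Stores raw axes, min-max scaled axes (scaled over the full recording, not
#' per window) and the 3-D magnitude
#' `sqrt(ax_n^2 + ay_n^2 + az_n^2)` in `[0, sqrt(3)]`.
#'
#' @param t Time stamps, s, strictly increasing.
#' @param ax,ay,az Raw per-axis acceleration, device units.
#' @return Data frame of class `accel_trace` with columns `t`, `ax`, `ay`,
#'   `az`, `ax_n`, `ay_n`, `az_n`, `mag`.
#' @export
accel_trace <- function(t, ax, ay, az) {
  n <- length(t)
  if (n < 2 || length(ax) != n || length(ay) != n || length(az) != n) {
    stop("t, ax, ay, az must share length >= 2", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  ax_n <- minmax_scale(ax); ay_n <- minmax_scale(ay); az_n <- minmax_scale(az)
  out <- data.frame(t = t, ax = ax, ay = ay, az = az,
                    ax_n = ax_n, ay_n = ay_n, az_n = az_n,
                    mag = sqrt(ax_n^2 + ay_n^2 + az_n^2))
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' 3-D magnitude of a scaled accelerometer trace
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector in `[0, sqrt(3)]`.
#' @export
accel_magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  trace$mag
}

#' Windowed CV of accelerometer magnitude (CV_accel)
#'
#' The magnitude is first downsampled to 1 Hz by per-second means, then the
#' same non-overlapping-window CV machinery as for the flow trace is applied.
#'
#' @param trace An [accel_trace()].
#' @param window_s Window length, s (default 300).
#' @param anchor Anchor time, s (default 0).
#' @param subject_id,group Labels carried into the result.
#' @return A [cv_series()] of CV_accel values.
#' @export
cv_accel <- function(trace, window_s = 300, anchor = 0,
                     subject_id = "subject", group = "NA") {
  stopifnot(inherits(trace, "accel_trace"))
  sec <- floor(trace$t)
  m1 <- vapply(split(trace$mag, sec), mean, numeric(1))
  t1 <- as.numeric(names(m1))
  ord <- order(t1)
  w <- .windowed_cv(t1[ord], m1[ord], window_s, anchor)
  cv_series(w$window_center, w$cv, subject_id = subject_id, group = group)
}

#' Flow/motion independence regression
#'
#' OLS of CV_CBFi on CV_accel over matched windows, with the two-sided slope
#' t-test. Used to check that motion does not explain flow variability
#' (sham and phantom scenarios).
#'
#' @param cv_flow,cv_motion [cv_series()] on identical window grids.
#' @return A `regression_result`.
#' @export
independence_test <- function(cv_flow, cv_motion) {
  stopifnot(inherits(cv_flow, "cv_series"), inherits(cv_motion, "cv_series"))
  if (nrow(cv_flow) != nrow(cv_motion) ||
      any(abs(cv_flow$window_center - cv_motion$window_center) > 1e-9)) {
    stop("window grids do not match between flow and motion CV series", call. = FALSE)
  }
  .ols_slope(cv_motion$cv, cv_flow$cv)
}

#' Read an accelerometer log from delimited text
#'
#' Expects a header with columns `t`, `x`, `y`, `z`.
#'
#' @param path CSV path.
#' @return An [accel_trace()].
#' @export
read_accel <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("accelerometer file must have columns t, x, y, z", call. = FALSE)
  }
  df <- df[order(df$t), ]
  accel_trace(df$t, df$x, df$y, df$z)
}
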
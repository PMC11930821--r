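#' Coefficient of variation
#'
#' `CV = s / mean(x)` with the sample (denominator n-1) standard deviation.
#'
#' @param x Numeric vector, length >= 2, non-zero mean.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stop("need at least 2 values for a CV", call. = FALSE)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  stats::sd(x) / m
}

# shared tiling machinery: non-overlapping windows of window_s seconds
# starting at the anchor; incomplete trailing window dropped.
.windowed_cv <- function(t, x, window_s, anchor) {
  sel <- t >= anchor
  t <- t[sel]; x <- x[sel]
  if (length(t) == 0 || (max(t) - anchor + 1) < window_s) {
    stop("trace spans less than one full ", window_s, "-s window after the anchor",
         call. = FALSE)
  }
  k <- floor((max(t) - anchor + 1) / window_s)
  idx <- floor((t - anchor) / window_s)
  keep <- idx < k
  cv <- vapply(split(x[keep], idx[keep]), coefficient_of_variation, numeric(1))
  centers <- (as.numeric(names(cv)) + 0.5) * window_s / 60  # minutes post-anchor
  ord <- order(centers)
  list(window_center = centers[ord], cv = unname(cv[ord]))
}

#' Per-window coefficient of variation series
#'
#' @param window_center Window centers, minutes since the anchor, strictly
#'   increasing.
#' @param cv Non-negative CV values.
#' @param subject_id Subject label.
#' @param group Group label (`"IVH+"`, `"IVH-"`, `"sham"` or free text).
#' @return Data frame of class `cv_series` with columns `subject_id`,
#'   `group`, `window_center`, `cv`.
#' @export
cv_series <- function(window_center, cv, subject_id = "subject", group = "NA") {
  if (length(window_center) != length(cv)) stop("length mismatch", call. = FALSE)
  if (length(window_center) > 1 && any(diff(window_center) <= 0)) {
    stop("window_center must be strictly increasing", call. = FALSE)
  }
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  out <- data.frame(subject_id = subject_id, group = group,
                    window_center = window_center, cv = cv)
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Windowed CV of a CBFi trace
#'
#' Consecutive non-overlapping windows (default 300 s = 5 min) aligned to the
#' anchor (injection time); the CV is computed on the smoothed series within
#' each complete window and the incomplete trailing window is dropped.
#'
#' @param trace A `cbfi_trace` (see [cbfi_trace()]).
#' @param window_s Window length, s (default 300).
#' @param anchor Anchor time, s (injection; windows start here). Default 0.
#' @param use_smooth Compute CV on `cbfi_smooth` (default) or raw `cbfi`.
#' @param subject_id,group Labels carried into the result.
#' @return A [cv_series()] with `window_center` in minutes post-anchor.
#' @export
windowed_cv <- function(trace, window_s = 300, anchor = 0, use_smooth = TRUE,
                        subject_id = "subject", group = "NA") {
  stopifnot(inherits(trace, "cbfi_trace"))
  x <- if (use_smooth) trace$cbfi_smooth else trace$cbfi
  ok <- is.finite(x)
  w <- .windowed_cv(trace$t[ok], x[ok], window_s, anchor)
  cv_series(w$window_center, w$cv, subject_id = subject_id, group = group)
}

# closed-form simple OLS with slope t-test, shared by all regression entry
# points (avoids lm() overhead in the large calibration simulations)
.ols_slope <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points for slope inference", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: all x identical", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, slope_se = se,
                 t_stat = tstat, p_value = p, n_points = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.4g +/- %.4g (SE), t = %.3g, p = %.3g, n = %d\n",
              x$slope, x$slope_se, x$t_stat, x$p_value, x$n_points))
  invisible(x)
}

#' Linear trend of a CV series
#'
#' Ordinary least squares of CV on window center, with the two-sided slope
#' t-test on n - 2 degrees of freedom.
#'
#' @param series A [cv_series()].
#' @return A `regression_result` with `slope` (CV per min), `intercept`,
#'   `slope_se`, `t_stat`, `p_value`, `n_points`.
#' @export
fit_cv_slope <- function(series) {
  stopifnot(inherits(series, "cv_series"))
  .ols_slope(series$window_center, series$cv)
}

#' Pooled CV-trend regression across subjects
#'
#' All (window center, CV) points from all subjects enter a single OLS fit
#' with points treated as exchangeable (no per-subject random effects),
#' matching a pooled cohort presentation; per-subject fits are returned
#' alongside.
#'
#' @param series_list Non-empty list of [cv_series()].
#' @return List with `pooled` (a `regression_result`) and `per_subject`
#'   (named list of `regression_result`).
#' @export
pooled_cv_regression <- function(series_list) {
  if (length(series_list) == 0) stop("empty series list", call. = FALSE)
  lapply(series_list, function(s) stopifnot(inherits(s, "cv_series")))
  all_df <- do.call(rbind, lapply(series_list, as.data.frame))
  pooled <- .ols_slope(all_df$window_center, all_df$cv)
  per <- lapply(series_list, fit_cv_slope)
  names(per) <- vapply(series_list, function(s) s$subject_id[1], character(1))
  list(pooled = pooled, per_subject = per)
}

#' Write per-window CV table(s) as delimited text
#'
#' @param series_list A [cv_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(series_list, path) {
  if (inherits(series_list, "cv_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  names(df)[names(df) == "window_center"] <- "window_center_min"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write regression summaries as delimited text
#'
#' @param results Named list of `regression_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regression_summary <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(fit = nm, slope = r$slope, intercept = r$intercept,
               slope_se = r$slope_se, t_stat = r$t_stat,
               p_value = r$p_value, n_points = r$n_points)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
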
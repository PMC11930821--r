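#' A single measured intensity autocorrelation curve
#'
#' @param t_acq Acquisition timestamp, seconds from record start.
#' @param tau Lag array, s (positive, sorted ascending, length >= 10).
#' @param g2 Measured intensity autocorrelation values (same length as `tau`).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(t_acq, tau, g2) {
  if (!is.numeric(t_acq) || length(t_acq) != 1 || !is.finite(t_acq)) {
    stop("t_acq must be a single finite number", call. = FALSE)
  }
  if (length(tau) != length(g2)) stop("tau and g2 must have equal length", call. = FALSE)
  if (length(tau) < 10) stop("a correlation curve needs at least 10 lags", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be finite and positive", call. = FALSE)
  if (is.unsorted(tau)) stop("tau must be sorted ascending", call. = FALSE)
  if (any(!is.finite(g2))) stop("g2 must be finite", call. = FALSE)
  structure(list(t_acq = t_acq, tau = as.numeric(tau), g2 = as.numeric(g2)),
            class = "correlation_curve")
}

#' Fitting options for g2-curve inversion
#'
#' @param bfi_max Upper bound on the fitted flow index, cm^2/s. The default
#'   1e-5 is a generous physiologic ceiling.
#' @param k_beta Number of earliest lags averaged by [estimate_beta()].
#' @param lag_keep_frac Lags are kept while `g2 - 1 > lag_keep_frac * beta0`;
#'   the deep tail of the curve is noise-dominated and excluded from the loss.
#' @param fix_beta If `TRUE`, [fit_trace()] freezes beta at the mean
#'   [estimate_beta()] of the first minute instead of fitting it per curve.
#' @param grid_points Coarse log-spaced bfi values searched before the 1-D
#'   refinement (serves as the multi-start safeguard).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(bfi_max = 1e-5, k_beta = 5, lag_keep_frac = 0.01,
                        fix_beta = FALSE, grid_points = 60) {
  stopifnot(bfi_max > 0, k_beta >= 1, lag_keep_frac >= 0, grid_points >= 10)
  structure(list(bfi_max = bfi_max, k_beta = k_beta,
                 lag_keep_frac = lag_keep_frac, fix_beta = fix_beta,
                 grid_points = grid_points),
            class = "fit_options")
}

#' Initial coherence-factor estimate from the early-lag plateau
#'
#' At lags much shorter than the decay time, `g2 - 1` plateaus at beta; the
#' mean over the earliest `k` lags, clipped to (0.01, 1], initializes the fit.
#'
#' @param curve A [correlation_curve()].
#' @param k Number of earliest lags to average (default 5).
#' @return Initial beta estimate in (0.01, 1].
#' @export
estimate_beta <- function(curve, k = 5) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(curve$tau) < k) stop("curve has fewer than k lags", call. = FALSE)
  b0 <- mean(curve$g2[seq_len(k)] - 1)
  min(max(b0, 0.01), 1.0)
}

# profile SSE over bfi: beta is linear in the model (g2 - 1 = beta * g1^2),
# so for each candidate bfi the optimal beta has the closed form
# sum(y * h) / sum(h^2), clipped to (0, 1].
.profile_sse <- function(bfi, tau, y, optics, geom, beta_fixed = NULL) {
  h <- g1_model(tau, bfi, optics, geom)^2
  beta <- if (is.null(beta_fixed)) {
    min(max(sum(y * h) / sum(h * h), 1e-6), 1)
  } else beta_fixed
  r <- y - beta * h
  list(sse = sum(r * r), beta = beta)
}

#' Fit one g2 curve for the blood flow index
#'
#' Least-squares inversion of the Siegert/correlation-diffusion forward model
#' over `(bfi, beta)`. Beta is profiled out in closed form (the model is
#' linear in beta at fixed bfi) and bfi is located by a coarse log-spaced
#' search followed by golden-section refinement on log10(bfi), with an
#' explicit check of the `bfi = 0` boundary. Optimizer failure is reported
#' via `converged = FALSE`, not an error.
#'
#' @param curve A [correlation_curve()].
#' @param optics An [optical_config()].
#' @param options A [fit_options()].
#' @param beta_fixed Optional fixed beta (used by `fix_beta` trace fits).
#' @return A list of class `fit_result` with `bfi_hat`, `beta_hat`,
#'   `residual_rms`, `converged`.
#' @export
fit_g2_curve <- function(curve, optics, options = fit_options(),
                         beta_fixed = NULL) {
  stopifnot(inherits(curve, "correlation_curve"), inherits(optics, "optical_config"))
  geom <- derive_geometry(optics)
  beta0 <- estimate_beta(curve, k = min(options$k_beta, length(curve$tau)))
  keep <- (curve$g2 - 1) > options$lag_keep_frac * beta0
  if (sum(keep) < 5) keep <- rep(TRUE, length(curve$tau))
  tau <- curve$tau[keep]
  y <- curve$g2[keep] - 1

  res <- tryCatch({
    sse_at <- function(lb) .profile_sse(10^lb, tau, y, optics, geom, beta_fixed)$sse
    lb_lo <- -12
    lb_hi <- log10(options$bfi_max)
    grid <- seq(lb_lo, lb_hi, length.out = options$grid_points)
    sse_grid <- vapply(grid, sse_at, numeric(1))
    i <- which.min(sse_grid)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(sse_at, lower = lo, upper = hi, tol = 1e-11)
    bfi_hat <- 10^opt$minimum
    best <- .profile_sse(bfi_hat, tau, y, optics, geom, beta_fixed)
    # boundary: a curve with no resolvable decay belongs at bfi = 0
    zero <- .profile_sse(0, tau, y, optics, geom, beta_fixed)
    if (zero$sse <= best$sse * (1 + 1e-12) + 1e-300) {
      bfi_hat <- 0
      best <- zero
    }
    list(bfi_hat = bfi_hat, beta_hat = best$beta,
         residual_rms = sqrt(best$sse / length(y)),
         converged = TRUE)
  }, error = function(e) {
    list(bfi_hat = NA_real_, beta_hat = NA_real_, residual_rms = NA_real_,
         converged = FALSE)
  })

  if (isTRUE(res$converged) &&
      (!is.finite(res$residual_rms) ||
       res$bfi_hat >= options$bfi_max * (1 - 1e-9))) {
    res$converged <- FALSE
  }
  structure(res, class = "fit_result")
}

#' Centered gap-aware moving mean
#'
#' An even window of length `w` at 1 Hz is centered as `floor(w/2)` samples
#' before and `floor(w/2) - 1` after the current sample (8 s default: 4
#' before, current, 3 after), shrinking at the record edges. Samples flagged
#' invalid are excluded from every window ("gap-aware"); a window with no
#' valid sample yields `NA`.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (default 8).
#' @param valid Logical vector marking usable samples (default all).
#' @return Numeric vector, same length as `x`.
#' @export
moving_mean <- function(x, window = 8, valid = rep(TRUE, length(x))) {
  n <- length(x)
  stopifnot(window >= 1, length(valid) == n)
  before <- floor(window / 2)
  after <- window - before - 1L
  xv <- ifelse(valid & is.finite(x), x, 0)
  cv <- as.numeric(valid & is.finite(x))
  cx <- c(0, cumsum(xv))
  cc <- c(0, cumsum(cv))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  s <- cx[hi + 1L] - cx[lo]
  m <- cc[hi + 1L] - cc[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out
}

#' Fit a full CBFi trace from a sequence of g2 curves
#'
#' Fits every curve (1 Hz acquisition), then applies the 8-s centered moving
#' mean; non-converged points are excluded from the smoothing windows.
#'
#' @param curves A list of [correlation_curve()] ordered by `t_acq` at
#'   approximately 1 s spacing.
#' @param optics An [optical_config()].
#' @param options A [fit_options()]. With `fix_beta = TRUE`, beta is frozen at
#'   the mean early-lag estimate over the first 60 curves.
#' @param smoothing_s Moving-mean window, s (default 8).
#' @return A `cbfi_trace`: data frame with columns `t`, `cbfi`, `cbfi_smooth`,
#'   `beta_hat`, `residual_rms`, `converged`.
#' @export
fit_trace <- function(curves, optics, options = fit_options(), smoothing_s = 8) {
  if (length(curves) == 0) stop("no curves supplied", call. = FALSE)
  t_acq <- vapply(curves, function(cu) cu$t_acq, numeric(1))
  if (is.unsorted(t_acq)) stop("curves must be ordered by t_acq", call. = FALSE)
  beta_fixed <- NULL
  if (isTRUE(options$fix_beta)) {
    head_idx <- seq_len(min(60L, length(curves)))
    beta_fixed <- mean(vapply(curves[head_idx], estimate_beta, numeric(1),
                              k = options$k_beta))
  }
  fits <- lapply(curves, fit_g2_curve, optics = optics, options = options,
                 beta_fixed = beta_fixed)
  cbfi_trace(
    t = t_acq,
    cbfi = vapply(fits, `[[`, numeric(1), "bfi_hat"),
    beta_hat = vapply(fits, `[[`, numeric(1), "beta_hat"),
    residual_rms = vapply(fits, `[[`, numeric(1), "residual_rms"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    smoothing_s = smoothing_s
  )
}

#' Construct a CBFi trace (1 Hz flow-index time series)
#'
#' Builds the smoothed series with the centered gap-aware moving mean. Used
#' both by [fit_trace()] and directly on simulated ground-truth flow.
#'
#' @param t Time stamps, s, strictly increasing.
#' @param cbfi Flow index values, cm^2/s.
#' @param beta_hat,residual_rms,converged Optional per-point fit diagnostics.
#' @param smoothing_s Moving-mean window, s (default 8).
#' @return Data frame of class `cbfi_trace`.
#' @export
cbfi_trace <- function(t, cbfi, beta_hat = NA_real_, residual_rms = NA_real_,
                       converged = TRUE, smoothing_s = 8) {
  if (length(t) != length(cbfi) || length(t) == 0) {
    stop("t and cbfi must be non-empty and of equal length", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  converged <- rep_len(converged, length(t))
  sm <- moving_mean(cbfi, window = smoothing_s, valid = converged)
  out <- data.frame(t = t, cbfi = cbfi, cbfi_smooth = sm,
                    beta_hat = rep_len(beta_hat, length(t)),
                    residual_rms = rep_len(residual_rms, length(t)),
                    converged = converged)
  attr(out, "smoothing_s") <- smoothing_s
  class(out) <- c("cbfi_trace", "data.frame")
  out
}

#' Read long-format g2 curves from delimited text
#'
#' Expects a header with columns `t_acq`, `tau`, `g2`; one row per lag, one
#' curve per distinct `t_acq`.
#'
#' @param path File path (CSV, UTF-8).
#' @return List of [correlation_curve()] ordered by acquisition time.
#' @export
read_g2_curves <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_acq", "tau", "g2")
  if (!all(need %in% names(df))) {
    stop("curve file must have columns t_acq, tau, g2", call. = FALSE)
  }
  curves <- lapply(split(df, df$t_acq), function(d) {
    d <- d[order(d$tau), ]
    correlation_curve(d$t_acq[1], d$tau, d$g2)
  })
  names(curves) <- NULL
  curves[order(vapply(curves, `[[`, numeric(1), "t_acq"))]
}

#' Write a fitted CBFi trace as delimited text
#'
#' @param trace A `cbfi_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cbfi_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cbfi_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
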
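#' Scenario configuration for the synthetic session generator
#'
#' The defaults state the experimental world being emulated: a ~5 min
#' baseline followed by >= 60 min of post-injection recording at 1 Hz, flow
#' fluctuations band-limited below 0.25 Hz whose relative amplitude (the
#' target CV of the flow series) ramps linearly after the injection, and
#' motion statistically independent of flow.
#'
#' @param seed Integer RNG seed. Flow, motion and image streams use seeds
#'   derived from it (`seed`, `seed + 1e6`, `seed + 2e6`) so they are
#'   mutually independent; R's default Mersenne-Twister is used throughout.
#' @param duration_s Total record length, s (default 3900 = 300 s baseline
#'   followed by 3600 s of post-injection recording).
#' @param baseline_s Pre-injection baseline length, s (default 300).
#' @param bfi_baseline Baseline flow index, cm^2/s (default 1e-8, a typical
#'   tissue value).
#' @param fluct_band Flow fluctuation band `c(f_lo, f_hi)`, Hz (default
#'   `c(0.01, 0.25)`).
#' @param cv_start,cv_end Target sigma/mu of the flow series at scenario
#'   start and end; the fluctuation amplitude ramps linearly from `cv_start`
#'   to `cv_end` between the end of the baseline and the end of the record.
#' @param g2_noise_sigma Multiplicative Gaussian noise level on `g2 - 1`
#'   (default 0.02).
#' @param beta_true True coherence factor (default 0.5).
#' @param accel_profile List of motion parameters for [simulate_accel()].
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, duration_s = 3900, baseline_s = 300,
                            bfi_baseline = 1e-8, fluct_band = c(0.01, 0.25),
                            cv_start = 0.05, cv_end = 0.20,
                            g2_noise_sigma = 0.02, beta_true = 0.5,
                            accel_profile = list()) {
  if (!(cv_start >= 0 && cv_end >= cv_start && cv_end < 1)) {
    stop("need 0 <= cv_start <= cv_end < 1", call. = FALSE)
  }
  if (fluct_band[2] > 0.5) stop("f_hi exceeds the Nyquist frequency at 1 Hz", call. = FALSE)
  if (fluct_band[1] < 0 || fluct_band[1] >= fluct_band[2]) stop("invalid fluct_band", call. = FALSE)
  if (duration_s <= baseline_s) stop("duration_s must exceed baseline_s", call. = FALSE)
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 baseline_s = baseline_s, bfi_baseline = bfi_baseline,
                 fluct_band = fluct_band, cv_start = cv_start, cv_end = cv_end,
                 g2_noise_sigma = g2_noise_sigma, beta_true = beta_true,
                 accel_profile = accel_profile),
            class = "scenario_config")
}

# unit-variance Gaussian noise band-limited by FFT masking: white noise is
# transformed, bins outside [f_lo, f_hi] are zeroed (conjugate-symmetrically),
# and the real inverse transform is standardized to mean 0, sd 1.
.bandlimited_noise <- function(n, fs, band) {
  z <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop("fluct_band contains no resolvable frequency bin", call. = FALSE)
  Z <- stats::fft(z)
  Z[!keep] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Simulate the ground-truth flow-index time series
#'
#' `bfi(t) = bfi_baseline * (1 + a(t) z(t))` at 1 Hz, where `z` is
#' unit-variance Gaussian noise band-limited to `fluct_band` and the
#' amplitude `a(t)` equals `cv_start` during the baseline then ramps
#' linearly to `cv_end` at the end of the record. Values are clipped below
#' at `bfi_baseline / 10`. Deterministic given the seed.
#'
#' @param cfg A [scenario_config()].
#' @return Data frame with columns `t` (s) and `bfi` (cm^2/s), plus the
#'   amplitude schedule `a`.
#' @export
simulate_bfi_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$duration_s
  t <- seq_len(n) - 1
  a <- ifelse(t < cfg$baseline_s, cfg$cv_start,
              cfg$cv_start + (cfg$cv_end - cfg$cv_start) *
                (t - cfg$baseline_s) / (cfg$duration_s - cfg$baseline_s))
  if (cfg$cv_end == 0) {
    bfi <- rep(cfg$bfi_baseline, n)
  } else {
    set.seed(cfg$seed)
    z <- .bandlimited_noise(n, fs = 1, band = cfg$fluct_band)
    bfi <- pmax(cfg$bfi_baseline * (1 + a * z), cfg$bfi_baseline / 10)
  }
  data.frame(t = t, bfi = bfi, a = a)
}

#' Emit noisy correlation curves from a flow time series
#'
#' One g2 curve per second from the forward model, with iid multiplicative
#' Gaussian noise on the decaying part:
#' `g2_obs = 1 + (g2 - 1) (1 + eps)`, `eps ~ N(0, g2_noise_sigma^2)` per lag.
#'
#' @param bfi_t Data frame with columns `t`, `bfi` (e.g. from
#'   [simulate_bfi_timeseries()]).
#' @param optics An [optical_config()].
#' @param beta_true Coherence factor.
#' @param g2_noise_sigma Noise level (0 reproduces the model exactly).
#' @param seed RNG seed.
#' @param tau Lag grid, s (default [dcs_lag_grid()]).
#' @return List of [correlation_curve()].
#' @export
emit_correlation_curves <- function(bfi_t, optics, beta_true = 0.5,
                                    g2_noise_sigma = 0.02, seed = 1,
                                    tau = dcs_lag_grid()) {
  stopifnot(is.data.frame(bfi_t), all(c("t", "bfi") %in% names(bfi_t)))
  geom <- derive_geometry(optics)
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(bfi_t)), function(i) {
    g2 <- 1 + beta_true * g1_model(tau, bfi_t$bfi[i], optics, geom)^2
    if (g2_noise_sigma > 0) {
      g2 <- 1 + (g2 - 1) * (1 + stats::rnorm(length(tau), sd = g2_noise_sigma))
    }
    correlation_curve(bfi_t$t[i], tau, g2)
  })
}

#' Phantom configuration (viscosity-controlled Brownian "flow")
#'
#' Emulates an intralipid emulsion whose Brownian diffusion coefficient is
#' set by the solution viscosity at fixed temperature (Stokes-Einstein:
#' `Db` proportional to `1/viscosity`). The laboratory realization uses
#' glycerol to tune viscosity; here the phantom is parameterized by
#' viscosity directly.
#'
#' @param viscosity_ref Reference viscosity, Pa s.
#' @param viscosity Actual viscosity, Pa s.
#' @param db_ref Brownian diffusion coefficient at the reference viscosity,
#'   cm^2/s.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(viscosity_ref = 1e-3, viscosity = 1e-3,
                           db_ref = 1e-8) {
  if (viscosity <= 0 || viscosity_ref <= 0) stop("viscosities must be positive", call. = FALSE)
  if (db_ref <= 0) stop("db_ref must be positive", call. = FALSE)
  structure(list(viscosity_ref = viscosity_ref, viscosity = viscosity,
                 db_ref = db_ref),
            class = "phantom_config")
}

#' Simulate a stationary optical-phantom recording
#'
#' Scales the Brownian diffusion coefficient by Stokes-Einstein
#' (`db = db_ref * viscosity_ref / viscosity`), emits a stationary curve
#' record at that flow level plus an independent accelerometer trace.
#'
#' @param cfg A [phantom_config()].
#' @param duration_s Record length, s (default 1200).
#' @param optics An [optical_config()].
#' @param beta_true Coherence factor.
#' @param g2_noise_sigma g2 noise level.
#' @param flow_jitter_cv Small stationary relative fluctuation of the
#'   phantom "flow" (Brownian systems are not perfectly still; default 0.02).
#' @param seed RNG seed.
#' @param tau Lag grid.
#' @return List with `db` (effective bfi, cm^2/s), `bfi_t`, `curves`,
#'   `accel`.
#' @export
simulate_phantom <- function(cfg, duration_s = 1200, optics = optical_config(),
                             beta_true = 0.5, g2_noise_sigma = 0.02,
                             flow_jitter_cv = 0.02, seed = 1,
                             tau = dcs_lag_grid()) {
  stopifnot(inherits(cfg, "phantom_config"))
  db <- cfg$db_ref * cfg$viscosity_ref / cfg$viscosity
  scen <- scenario_config(seed = seed, duration_s = duration_s,
                          baseline_s = duration_s - 1, bfi_baseline = db,
                          cv_start = flow_jitter_cv, cv_end = flow_jitter_cv,
                          g2_noise_sigma = g2_noise_sigma,
                          beta_true = beta_true)
  bfi_t <- simulate_bfi_timeseries(scen)
  curves <- emit_correlation_curves(bfi_t, optics, beta_true, g2_noise_sigma,
                                    seed = seed + 1000L, tau = tau)
  accel <- simulate_accel(duration_s, seed = seed + 1000000L)
  list(db = db, bfi_t = bfi_t, curves = curves, accel = accel)
}

#' Simulate a three-axis accelerometer log
#'
#' Per axis: a slow random-walk drift plus Gaussian jitter, then an
#' arbitrary per-axis gain and offset (exercising the min-max invariance of
#' the downstream analysis). Uses its own RNG stream so motion is
#' statistically independent of the flow generator.
#'
#' @param duration_s Record length, s.
#' @param profile List: `fs` sampling rate Hz (default 25), `jitter_sd`,
#'   `drift_sd` (per-sample random-walk increment sd), `gains`, `offsets`
#'   (length-3).
#' @param seed RNG seed for the motion stream.
#' @return An [accel_trace()].
#' @export
simulate_accel <- function(duration_s, profile = list(), seed = 1) {
  p <- utils::modifyList(list(fs = 25, jitter_sd = 0.02, drift_sd = 0.005,
                              gains = c(1, 1, 1), offsets = c(0, 0, 0)),
                         profile)
  n <- round(duration_s * p$fs)
  set.seed(as.integer(seed))
  mk_axis <- function(g, o) {
    x <- cumsum(stats::rnorm(n, sd = p$drift_sd)) + stats::rnorm(n, sd = p$jitter_sd)
    g * x + o
  }
  t <- (seq_len(n) - 1) / p$fs
  accel_trace(t, mk_axis(p$gains[1], p$offsets[1]),
              mk_axis(p$gains[2], p$offsets[2]),
              mk_axis(p$gains[3], p$offsets[3]))
}

#' Simulate an ultrasound-like image series with a brightening ROI
#'
#' Speckle-like frames of iid gamma-distributed pixels; the ROI mean is
#' raised according to a multiplicative brightening schedule (relative to
#' the background mean), emulating the emergence of ventricular
#' hyperechogenicity.
#'
#' @param n_frames Number of frames.
#' @param roi ROI list as in [echo_frame()].
#' @param brightening_schedule Numeric vector, length `n_frames`: ROI mean as
#'   a multiple of the background mean.
#' @param seed RNG seed for the image stream.
#' @param dims Image dimensions `c(rows, cols)` (default `c(128, 128)`).
#' @param bg_mean Background mean intensity (default 40, 8-bit-like).
#' @param gamma_shape Speckle shape parameter (default 4; sd/mean = 0.5).
#' @param timestamps_min Optional per-frame acquisition times, min.
#' @return List of [echo_frame()].
#' @export
simulate_echo_series <- function(n_frames, roi, brightening_schedule, seed = 1,
                                 dims = c(128, 128), bg_mean = 40,
                                 gamma_shape = 4, timestamps_min = NULL) {
  if (length(brightening_schedule) != n_frames) {
    stop("brightening_schedule length must equal n_frames", call. = FALSE)
  }
  if (is.null(timestamps_min)) timestamps_min <- seq_len(n_frames)
  set.seed(as.integer(seed))
  # validate ROI bounds once via a probe frame
  probe <- echo_frame(matrix(0, dims[1], dims[2]), roi)
  mask <- roi_mask(probe)
  lapply(seq_len(n_frames), function(i) {
    px <- matrix(stats::rgamma(prod(dims), shape = gamma_shape,
                               scale = bg_mean / gamma_shape),
                 dims[1], dims[2])
    mean_roi <- brightening_schedule[i] * bg_mean
    px[mask] <- stats::rgamma(sum(mask), shape = gamma_shape,
                              scale = mean_roi / gamma_shape)
    echo_frame(px, roi, timestamp_min = timestamps_min[i])
  })
}

#' Write a complete synthetic session to a directory
#'
#' Emits everything the file-based pipeline consumes: `curves.csv`
#' (long-format g2), `accel.csv`, `truth.csv` (ground-truth bfi(t) and the
#' amplitude schedule), `echo_*.pgm` frames with `roi.json`, and
#' `scenario.json` echoing every generator parameter.
#'
#' @param dir Output directory (created if absent).
#' @param cfg A [scenario_config()].
#' @param optics An [optical_config()].
#' @param tau Lag grid for emitted curves.
#' @param n_echo_frames Number of ultrasound-like frames (default 4).
#' @return `dir`, invisibly.
#' @export
simulate_session <- function(dir, cfg = scenario_config(),
                             optics = optical_config(),
                             tau = dcs_lag_grid(points_per_decade = 8),
                             n_echo_frames = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bfi_t <- simulate_bfi_timeseries(cfg)
  curves <- emit_correlation_curves(bfi_t, optics, cfg$beta_true,
                                    cfg$g2_noise_sigma, seed = cfg$seed + 1000L,
                                    tau = tau)
  long <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(t_acq = cu$t_acq, tau = cu$tau, g2 = cu$g2)
  }))
  utils::write.csv(long, file.path(dir, "curves.csv"), row.names = FALSE)
  accel <- simulate_accel(cfg$duration_s, cfg$accel_profile,
                          seed = cfg$seed + 1000000L)
  utils::write.csv(data.frame(t = accel$t, x = accel$ax, y = accel$ay,
                              z = accel$az),
                   file.path(dir, "accel.csv"), row.names = FALSE)
  utils::write.csv(bfi_t, file.path(dir, "truth.csv"), row.names = FALSE)
  roi <- list(center_row = 40, center_col = 64, semi_row = 14, semi_col = 22)
  sched <- seq(1, 2.5, length.out = n_echo_frames)
  frames <- simulate_echo_series(n_echo_frames, roi, sched,
                                 seed = cfg$seed + 2000000L)
  for (i in seq_along(frames)) {
    write_gray_image(frames[[i]]$pixels,
                     file.path(dir, sprintf("echo_%02d.pgm", i)))
  }
  jsonlite::write_json(roi, file.path(dir, "roi.json"), auto_unbox = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
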
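test_that("scenario_config validates its stated world", {
  expect_error(scenario_config(cv_start = 0.3, cv_end = 0.1), "cv_start")
  expect_error(scenario_config(fluct_band = c(0.1, 0.6)), "Nyquist")
  expect_error(scenario_config(duration_s = 100, baseline_s = 300), "exceed")
})

test_that("flow generator is deterministic and honours degenerate targets", {
  cfg <- scenario_config(seed = 5, duration_s = 1200, baseline_s = 300)
  a <- simulate_bfi_timeseries(cfg)
  b <- simulate_bfi_timeseries(cfg)
  expect_identical(a, b)

  flat <- simulate_bfi_timeseries(scenario_config(seed = 5, duration_s = 600,
                                                  baseline_s = 100,
                                                  cv_start = 0, cv_end = 0))
  expect_equal(flat$bfi, rep(1e-8, 600))
  expect_true(all(a$bfi >= 1e-8 / 10))
})

test_that("stationary generator hits the target sigma/mu", {
  cfg <- scenario_config(seed = 6, duration_s = 7200, baseline_s = 100,
                         cv_start = 0.1, cv_end = 0.1)
  x <- simulate_bfi_timeseries(cfg)$bfi
  expect_equal(sd(x) / mean(x), 0.1, tolerance = 0.1 * 0.1)  # within 10%
})

test_that("generator fluctuation power stays inside the stated band", {
  cfg <- scenario_config(seed = 7, duration_s = 3900, baseline_s = 300)
  x <- simulate_bfi_timeseries(cfg)$bfi
  sp <- cbfi_spectrum(cbfi_trace(0:3899, x), band = c(0.002, 0.4))
  in_band <- sp$freq >= cfg$fluct_band[1] & sp$freq <= cfg$fluct_band[2]
  expect_gte(sum(sp$power_norm[in_band]), 0.9)
})

test_that("noiseless curve emission reproduces the forward model exactly", {
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 8)
  bfi_t <- data.frame(t = 0:29, bfi = seq(8e-9, 1.6e-8, length.out = 30))
  curves <- emit_correlation_curves(bfi_t, opt, 0.5, 0, seed = 2, tau = tau)
  expect_equal(curves[[7]]$g2,
               g2_model(tau, flow_state(bfi_t$bfi[7], 0.5), opt))
  tr <- fit_trace(curves, opt)
  expect_lt(max(abs(tr$cbfi - bfi_t$bfi) / bfi_t$bfi), 1e-6)
})

test_that("noisy emission yields near-unbiased per-second fits", {
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 16)
  bfi_t <- data.frame(t = 0:199, bfi = rep(1e-8, 200))
  curves <- emit_correlation_curves(bfi_t, opt, 0.5, 0.02, seed = 3, tau = tau)
  tr <- fit_trace(curves, opt)
  expect_lt(abs(mean(tr$cbfi) - 1e-8), 0.01 * 1e-8)
})

test_that("phantom obeys Stokes-Einstein scaling", {
  expect_equal(phantom_config(viscosity_ref = 1e-3, viscosity = 1e-3,
                              db_ref = 1e-8)$db_ref, 1e-8)
  expect_error(phantom_config(viscosity = 0), "positive")

  opt <- paper_optics()
  ph1 <- simulate_phantom(phantom_config(1e-3, 1e-3, 1e-8), duration_s = 30,
                          optics = opt, g2_noise_sigma = 0, flow_jitter_cv = 0,
                          seed = 4, tau = dcs_lag_grid(points_per_decade = 8))
  expect_equal(ph1$db, 1e-8)
  ph2 <- simulate_phantom(phantom_config(1e-3, 2e-3, 1e-8), duration_s = 30,
                          optics = opt, g2_noise_sigma = 0, flow_jitter_cv = 0,
                          seed = 4, tau = dcs_lag_grid(points_per_decade = 8))
  expect_equal(ph2$db, 5e-9)
  f1 <- fit_trace(ph1$curves, opt)$cbfi[1]
  f2 <- fit_trace(ph2$curves, opt)$cbfi[1]
  expect_lt(abs(f2 / f1 - 0.5), 0.02 * 0.5)  # doubling viscosity halves bfi
})

test_that("motion generator is seeded, independent, and affine-exercised", {
  a <- simulate_accel(60, seed = 8)
  b <- simulate_accel(60, seed = 8)
  expect_identical(a, b)

  w <- capture_warnings(
    z <- simulate_accel(10, profile = list(jitter_sd = 0, drift_sd = 0), seed = 8))
  expect_length(w, 3)  # one per constant axis
  expect_true(all(grepl("constant axis", w)))
  expect_equal(z$mag, rep(0, nrow(z)))

  # per-axis gain/offset leaves the normalized magnitude unchanged
  g <- simulate_accel(60, profile = list(gains = c(10, 1, 1),
                                         offsets = c(3, 0, 0)), seed = 8)
  plain <- simulate_accel(60, seed = 8)
  expect_equal(g$mag, plain$mag, tolerance = 1e-12)
})

test_that("echo series realizes the brightening schedule", {
  roi <- list(center_row = 60, center_col = 60, semi_row = 25, semi_col = 30)
  sched <- c(1.0, 1.5, 2.8)
  frames <- simulate_echo_series(3, roi, sched, seed = 9)
  ratios <- vapply(frames, function(f)
    echogenicity_ratio(f, frames[[1]])$ratio, numeric(1))
  expect_equal(ratios, sched / sched[1], tolerance = 0.05)

  flat <- simulate_echo_series(4, roi, rep(1, 4), seed = 10)
  fr <- vapply(flat, function(f)
    echogenicity_ratio(f, flat[[1]])$ratio, numeric(1))
  expect_equal(fr, rep(1, 4), tolerance = 0.05)

  expect_error(simulate_echo_series(3, roi, c(1, 2)), "length")

  # sampling theory: a tiny ROI gives a noisier ratio than a large one
  roi_small <- list(center_row = 60, center_col = 60, semi_row = 1, semi_col = 2)
  many_big <- simulate_echo_series(30, roi, rep(1.5, 30), seed = 11)
  many_small <- simulate_echo_series(30, roi_small, rep(1.5, 30), seed = 11)
  ref_big <- simulate_echo_series(1, roi, 1, seed = 12)[[1]]
  ref_small <- simulate_echo_series(1, roi_small, 1, seed = 12)[[1]]
  v_big <- var(vapply(many_big, function(f)
    echogenicity_ratio(f, ref_big)$ratio, numeric(1)))
  v_small <- var(vapply(many_small, function(f)
    echogenicity_ratio(f, ref_small)$ratio, numeric(1)))
  expect_gt(v_small, v_big)
})

test_that("simulate_session writes a complete, reloadable session", {
  dir <- tempfile("session_")
  cfg <- scenario_config(seed = 13, duration_s = 620, baseline_s = 100)
  simulate_session(dir, cfg, n_echo_frames = 2)
  expect_true(all(file.exists(file.path(dir,
    c("curves.csv", "accel.csv", "truth.csv", "roi.json", "scenario.json",
      "echo_01.pgm", "echo_02.pgm")))))
  curves <- read_g2_curves(file.path(dir, "curves.csv"))
  expect_length(curves, 620)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 620)
  tr <- read_accel(file.path(dir, "accel.csv"))
  expect_s3_class(tr, "accel_trace")
})
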
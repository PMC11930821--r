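test_that("estimate_beta reads the early-lag plateau", {
  tau <- dcs_lag_grid(1e-7, 1e-2, 8)
  cu <- correlation_curve(0, tau, c(rep(1.5, 5), rep(1.2, length(tau) - 5)))
  expect_equal(estimate_beta(cu), 0.5)

  g2e <- c(1.48, 1.50, 1.52, 1.50, 1.50, rep(1.1, length(tau) - 5))
  expect_equal(estimate_beta(correlation_curve(0, tau, g2e)), 0.5)

  # forward-model oracle: noiseless curve with a small first lag
  cu <- noiseless_curve(1e-8, 0.45)
  expect_equal(estimate_beta(cu), 0.45, tolerance = 0.01)

  expect_error(estimate_beta(cu, k = 1e6), "fewer")
})

test_that("correlation_curve validates its contract", {
  tau <- dcs_lag_grid(1e-7, 1e-2, 8)
  expect_error(correlation_curve(0, tau[1:5], rep(1.2, 5)), "at least 10")
  expect_error(correlation_curve(0, tau, rep(1.2, 3)), "equal length")
  expect_error(correlation_curve(0, rev(tau), rep(1.2, length(tau))), "sorted")
  expect_error(correlation_curve(0, tau, rep(NA_real_, length(tau))), "finite")
})

test_that("noiseless fits round-trip the forward model", {
  opt <- paper_optics()
  for (bfi in c(1e-9, 1e-7)) {
    f <- fit_g2_curve(noiseless_curve(bfi, 0.5), opt)
    expect_true(f$converged)
    expect_lt(abs(f$bfi_hat - bfi) / bfi, 1e-6)
    expect_lt(abs(f$beta_hat - 0.5), 1e-6)
  }
})

test_that("a flat curve fits to the zero-flow boundary", {
  tau <- dcs_lag_grid()
  f <- fit_g2_curve(correlation_curve(0, tau, rep(1.5, length(tau))),
                    paper_optics())
  expect_identical(f$bfi_hat, 0)
  expect_equal(f$beta_hat, 0.5)
})

test_that("noisy recovery is accurate in the median (small Monte Carlo)", {
  set.seed(7)
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 16)
  g2_true <- g2_model(tau, flow_state(1e-8, 0.5), opt)
  err <- replicate(50, {
    g2n <- 1 + (g2_true - 1) * (1 + rnorm(length(tau), sd = 0.01))
    f <- fit_g2_curve(correlation_curve(0, tau, g2n), opt)
    abs(f$bfi_hat - 1e-8) / 1e-8
  })
  expect_lt(median(err), 0.05)
})

test_that("fit noise scales with injected g2 noise", {
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 16)
  g2_true <- g2_model(tau, flow_state(1e-8, 0.5), opt)
  v <- vapply(c(0.005, 0.02, 0.05), function(s) {
    set.seed(11)
    stats::var(replicate(40, {
      g2n <- 1 + (g2_true - 1) * (1 + rnorm(length(tau), sd = s))
      fit_g2_curve(correlation_curve(0, tau, g2n), opt)$bfi_hat
    }))
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("moving_mean matches a brute-force windowed oracle and handles gaps", {
  set.seed(3)
  x <- rnorm(40)
  w <- 8
  sm <- moving_mean(x, w)
  # brute force: centered window, floor(w/2) before and w - floor(w/2) - 1 after
  oracle <- vapply(seq_along(x), function(i) {
    idx <- max(1, i - 4):min(length(x), i + 3)
    mean(x[idx])
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-14)

  # gap-aware: invalid points are excluded from every window
  valid <- rep(TRUE, 40); valid[20] <- FALSE
  sm2 <- moving_mean(x, w, valid)
  oracle2 <- vapply(seq_along(x), function(i) {
    idx <- setdiff(max(1, i - 4):min(length(x), i + 3), 20)
    mean(x[idx])
  }, numeric(1))
  expect_equal(sm2, oracle2, tolerance = 1e-14)

  # smoothing of a constant is exact (mean preservation on flat segments)
  expect_equal(moving_mean(rep(3.5, 100), 8), rep(3.5, 100))
})

test_that("fit_trace smooths per contract", {
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 8)

  # identical noiseless curves: constant trace, smoothing is the identity
  curves <- lapply(0:19, function(t) noiseless_curve(1e-8, 0.5, tau = tau, t_acq = t))
  tr <- fit_trace(curves, opt)
  expect_equal(nrow(tr), 20)
  expect_equal(diff(tr$t), rep(1, 19))
  expect_lt(max(abs(tr$cbfi - 1e-8)) / 1e-8, 1e-6)
  expect_equal(tr$cbfi_smooth, tr$cbfi, tolerance = 1e-12)

  # single curve: degenerate window
  tr1 <- fit_trace(curves[1], opt)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$cbfi_smooth, tr1$cbfi)

  expect_error(fit_trace(list(), opt), "no curves")
})

test_that("a step in true flow crosses the midpoint within 4 s of the step", {
  # moving-mean oracle on the step sequence, using ideal (noiseless) fits
  bfi <- c(rep(1e-8, 30), rep(2e-8, 30))
  tr <- cbfi_trace(t = 0:59, cbfi = bfi, smoothing_s = 8)
  cross <- min(which(tr$cbfi_smooth >= 1.5e-8)) - 1  # time index
  expect_lte(abs(cross - 30), 4)
})

test_that("g2 curve reader/writer round-trips through the fit", {
  opt <- paper_optics()
  tau <- dcs_lag_grid(points_per_decade = 8)
  bfi_t <- data.frame(t = 0:9, bfi = seq(1e-8, 2e-8, length.out = 10))
  curves <- emit_correlation_curves(bfi_t, opt, 0.5, 0, seed = 1, tau = tau)
  long <- do.call(rbind, lapply(curves, function(cu)
    data.frame(t_acq = cu$t_acq, tau = cu$tau, g2 = cu$g2)))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(long, f, row.names = FALSE)
  back <- read_g2_curves(f)
  expect_length(back, 10)
  expect_equal(vapply(back, `[[`, numeric(1), "t_acq"), 0:9)
  tr <- fit_trace(back, opt)
  expect_lt(max(abs(tr$cbfi - bfi_t$bfi) / bfi_t$bfi), 1e-6)

  out <- tempfile(fileext = ".csv")
  write_cbfi_trace(tr, out)
  df <- utils::read.csv(out)
  expect_named(df, c("t", "cbfi", "cbfi_smooth", "beta_hat", "residual_rms",
                     "converged"))
})
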
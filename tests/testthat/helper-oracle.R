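# Independent closed-form oracle for the semi-infinite correlation diffusion
# solution, transcribed directly from the formula and kept deliberately
# separate from the package implementation path.
oracle_g1 <- function(tau, bfi, mu_a, mu_sp, lambda_nm, n_med, rho, n_out = 1) {
  n_rel <- n_med / n_out
  Reff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  z0 <- 1 / mu_sp
  zb <- (2 / 3) * (1 + Reff) / ((1 - Reff) * mu_sp)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  k0 <- 2 * pi * n_med / (lambda_nm * 1e-7)
  G <- function(tt) {
    K <- sqrt(3 * mu_a * mu_sp + 6 * mu_sp^2 * k0^2 * bfi * tt)
    exp(-K * r1) / r1 - exp(-K * rb) / rb
  }
  vapply(tau, G, numeric(1)) / G(0)
}

# Values frozen from a one-off 50-digit arbitrary-precision (mpmath)
# evaluation of the same closed form at mu_a = 0.1, mu_s' = 8.0, 785 nm,
# n = 1.4, rho = 0.5 cm, bfi = 1e-8 cm^2/s.
mpmath_pins <- list(
  tau = c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3),
  g1  = c(0.99949875562964729, 0.99501061154391897, 0.9522682845774223,
          0.65880418713870572, 0.085405664792502799),
  zb_n1   = 0.08360042735042735,   # extrapolation distance at n_rel = 1
  zb_n1.4 = 0.27089145511494811,
  r1 = 0.51538820320220757,
  rb = 0.83342633110230556,
  k0 = 112056.80802613275
)

# shared fixtures
paper_optics <- function() optical_config()  # defaults are the paper-world constants

noiseless_curve <- function(bfi, beta, optics = paper_optics(),
                            tau = dcs_lag_grid(), t_acq = 0) {
  correlation_curve(t_acq, tau, g2_model(tau, flow_state(bfi, beta), optics))
}
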
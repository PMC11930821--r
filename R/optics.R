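#' Optical and geometric configuration of a DCS measurement
#'
#' Bundles the tissue optical properties and probe geometry assumed fixed
#' during blood-flow-index fitting. Defaults are the constants used for the
#' neonatal measurements this package targets: `mu_a = 0.1` cm^-1,
#' `mu_s_prime = 8.0` cm^-1, a 785 nm source and a 5 mm (0.5 cm)
#' source-detector separation.
#'
#' @param mu_a Absorption coefficient, cm^-1.
#' @param mu_s_prime Reduced scattering coefficient, cm^-1.
#' @param wavelength Source wavelength, nm (converted to cm internally).
#' @param n_medium Tissue refractive index (dimensionless). Not reported for
#'   this preparation; 1.4 is the conventional soft-tissue value.
#' @param rho Source-detector separation, cm. Must exceed one transport mean
#'   free path `1/mu_s_prime` for the diffusion model to apply.
#'
#' @return An object of class `optical_config`.
#' @examples
#' optics <- optical_config()
#' derive_geometry(optics)
#' @export
optical_config <- function(mu_a = 0.1, mu_s_prime = 8.0, wavelength = 785,
                           n_medium = 1.4, rho = 0.5) {
  vals <- c(mu_a = mu_a, mu_s_prime = mu_s_prime, wavelength = wavelength,
            n_medium = n_medium, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid optical configuration: all fields must be finite and strictly positive",
         call. = FALSE)
  }
  if (mu_s_prime / mu_a < 10) {
    warning("mu_s_prime/mu_a < 10: diffusion approximation is questionable",
            call. = FALSE)
  }
  if (rho <= 1 / mu_s_prime) {
    stop("rho must exceed one transport mean free path (1/mu_s_prime = ",
         signif(1 / mu_s_prime, 4), " cm)", call. = FALSE)
  }
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, wavelength = wavelength,
                 n_medium = n_medium, rho = rho),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("DCS optical configuration\n")
  cat(sprintf("  mu_a        %.4g cm^-1\n", x$mu_a))
  cat(sprintf("  mu_s'       %.4g cm^-1\n", x$mu_s_prime))
  cat(sprintf("  wavelength  %.4g nm\n", x$wavelength))
  cat(sprintf("  n_medium    %.4g\n", x$n_medium))
  cat(sprintf("  rho         %.4g cm\n", x$rho))
  invisible(x)
}

#' Effective reflection coefficient for a refractive-index mismatch
#'
#' Polynomial approximation to the effective Fresnel reflection coefficient
#' entering the extrapolated-boundary condition, as a function of the
#' relative refractive index `n_rel = n_medium / n_outside`.
#'
#' @param n_rel Relative refractive index (medium over exterior).
#' @return Effective reflection coefficient in `[0, 1)`.
#' @export
effective_reflection <- function(n_rel) {
  if (!is.numeric(n_rel) || any(n_rel <= 0)) stop("n_rel must be positive", call. = FALSE)
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

#' Boundary-condition geometry for the semi-infinite diffusion model
#'
#' Computes the derived quantities of the extrapolated-boundary solution:
#' effective isotropic source depth `z0 = 1/mu_s_prime`, extrapolation
#' distance `zb = 2 (1 + R_eff) / (3 mu_s_prime (1 - R_eff))`, real and image
#' source distances `r1`, `rb`, and the in-medium wavenumber
#' `k0 = 2 pi n_medium / lambda`.
#'
#' @param optics An [optical_config()].
#' @param n_outside Refractive index of the exterior medium (default 1.0).
#' @return An object of class `model_geometry` with fields `z0`, `zb`, `r1`,
#'   `rb`, `k0`, `R_eff` (lengths in cm, `k0` in cm^-1).
#' @export
derive_geometry <- function(optics, n_outside = 1.0) {
  stopifnot(inherits(optics, "optical_config"))
  R_eff <- effective_reflection(optics$n_medium / n_outside)
  R_eff <- min(max(R_eff, 0), 1 - 1e-12)
  z0 <- 1 / optics$mu_s_prime
  zb <- 2 * (1 + R_eff) / (3 * optics$mu_s_prime * (1 - R_eff))
  lambda_cm <- optics$wavelength * 1e-7
  geom <- list(
    z0 = z0,
    zb = zb,
    r1 = sqrt(optics$rho^2 + z0^2),
    rb = sqrt(optics$rho^2 + (z0 + 2 * zb)^2),
    k0 = 2 * pi * optics$n_medium / lambda_cm,
    R_eff = R_eff
  )
  structure(geom, class = "model_geometry")
}

#' Logarithmic correlator-style lag grid
#'
#' Multi-tau hardware correlators report lags approximately log-spaced; this
#' builds a matching grid for simulation and fitting.
#'
#' @param tau_min,tau_max Lag range, s.
#' @param points_per_decade Grid density (default 64).
#' @return Sorted numeric vector of lags in seconds.
#' @export
dcs_lag_grid <- function(tau_min = 1e-7, tau_max = 1e-1, points_per_decade = 64) {
  if (tau_min <= 0 || tau_max <= tau_min) stop("need 0 < tau_min < tau_max", call. = FALSE)
  n <- ceiling(log10(tau_max / tau_min) * points_per_decade) + 1
  10^seq(log10(tau_min), log10(tau_max), length.out = n)
}
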
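#' Flow state of the correlation diffusion model
#'
#' @param bfi Blood flow index (effective Brownian diffusion coefficient
#'   alpha*Db), cm^2/s. Non-negative.
#' @param beta Siegert coherence factor, in (0, 1].
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(bfi, beta = 0.5) {
  if (!is.finite(bfi) || bfi < 0) stop("bfi must be finite and >= 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must lie in (0, 1]", call. = FALSE)
  structure(list(bfi = bfi, beta = beta), class = "flow_state")
}

# decay exponent K(tau) = sqrt(3 mu_a mu_s' + 6 mu_s'^2 k0^2 bfi tau)
# for Brownian dynamics <dr^2(tau)> = 6 bfi tau
.k_decay <- function(tau, bfi, optics, geom) {
  sqrt(3 * optics$mu_a * optics$mu_s_prime +
         6 * optics$mu_s_prime^2 * geom$k0^2 * bfi * tau)
}

.check_tau <- function(tau) {
  if (length(tau) == 0 || any(!is.finite(tau)) || any(tau < 0)) {
    stop("tau must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(tau)) stop("tau must be sorted ascending", call. = FALSE)
}

#' Normalized field autocorrelation g1(tau) for a semi-infinite medium
#'
#' Closed-form solution of the correlation diffusion equation for a
#' point source and detector on the surface of a semi-infinite homogeneous
#' turbid medium with Brownian scatterer dynamics and an extrapolated
#' zero boundary:
#' \deqn{g_1(\tau) = \frac{e^{-K(\tau) r_1}/r_1 - e^{-K(\tau) r_b}/r_b}
#'                       {e^{-K(0) r_1}/r_1 - e^{-K(0) r_b}/r_b},\quad
#'       K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\, \mathrm{BFi}\,\tau}.}
#'
#' @param tau Lag times, s (non-negative, sorted ascending).
#' @param flow A [flow_state()] (only `bfi` is used).
#' @param optics An [optical_config()].
#' @param geom Optional precomputed [derive_geometry()] result (saves work in
#'   tight fitting loops).
#' @return Numeric vector of g1 values in (0, 1], with `g1(0) = 1`.
#' @export
g1_model <- function(tau, flow, optics, geom = derive_geometry(optics)) {
  .check_tau(tau)
  bfi <- if (inherits(flow, "flow_state")) flow$bfi else flow
  if (!is.finite(bfi) || bfi < 0) stop("bfi must be finite and >= 0", call. = FALSE)
  K <- .k_decay(tau, bfi, optics, geom)
  K0 <- .k_decay(0, bfi, optics, geom)
  num <- exp(-K * geom$r1) / geom$r1 - exp(-K * geom$rb) / geom$rb
  den <- exp(-K0 * geom$r1) / geom$r1 - exp(-K0 * geom$rb) / geom$rb
  num / den
}

#' Normalized intensity autocorrelation g2(tau) via the Siegert relation
#'
#' `g2(tau) = 1 + beta * g1(tau)^2`, the quantity a photon-counting
#' correlator reports.
#'
#' @inheritParams g1_model
#' @param flow A [flow_state()]; both `bfi` and `beta` are used.
#' @return Numeric vector with `g2(0) = 1 + beta`, decaying to 1.
#' @export
g2_model <- function(tau, flow, optics, geom = derive_geometry(optics)) {
  if (!inherits(flow, "flow_state")) stop("flow must be a flow_state", call. = FALSE)
  1 + flow$beta * g1_model(tau, flow$bfi, optics, geom)^2
}
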
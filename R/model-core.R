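#' @include AllClasses.R
NULL

#' Construct the biological parameter set
#'
#' All constants of the coupled tumor-phase / oxygen system, in working units
#' (mm, day, mM, Pa). Defaults are the literature estimates for human brain
#' and glioblastoma: proliferation \code{nu_c = 0.3}/day (well-oxygenated GBM
#' cells double in 1-2 days in vitro; lower values are biologically admissible
#' in vivo), hypoxic-death threshold \code{delta_c = 0.3} (reported range
#' 0.28-0.5), physiological oxygen \code{n_s = 0.07} mM (range 0.07-0.28),
#' chemotactic coefficient \code{k_n = 100} mm^2 mM^-1 day^-1 (the tabulated
#' bacterial-chemotaxis estimate is 1296), interphase friction
#' \code{M = 5000} mm^-2 Pa day (inverse hydraulic conductivity estimates
#' span 1377.9-4286.7), Young's modulus \code{E = 694} Pa, equilibrium
#' fraction \code{phi_e = 0.389}, oxygen transfer \code{S_n = 1e4}/day,
#' uptake \code{delta_n = 8640}/day (\code{= D_n / l_n^2}, admissible range
#' 8640-15650), oxygen diffusivity \code{D_n = 86.4} mm^2/day, interstitial
#' fluid pressure \code{chi = 900} Pa (healthy brain 106.64 Pa, brain tumors
#' ~960 Pa), and oxygen penetration length \code{l_n = 0.1} mm. The interface
#' coefficient default \code{eps = sqrt(chi) * 0.015 = 0.45} follows the
#' dimensional reconstruction of [deriveInterfaceCoefficient()] with a 15 um
#' cell size.
#'
#' @param nu_c,delta_c,n_s,k_n,M,eps,E,phi_e,S_n,delta_n,D_n,chi,l_n see
#'   [ModelParameters-class] for units and meaning.
#' @return a validated [ModelParameters-class] object.
#' @examples
#' p <- modelParameters(nu_c = 1, k_n = 100)
#' p
#' @export
modelParameters <- function(nu_c = 0.3, delta_c = 0.3, n_s = 0.07, k_n = 100,
                            M = 5000, eps = 0.45, E = 694, phi_e = 0.389,
                            S_n = 1e4, delta_n = 8640, D_n = 86.4,
                            chi = 900, l_n = 0.1) {
  new("ModelParameters", nu_c = nu_c, delta_c = delta_c, n_s = n_s, k_n = k_n,
      M = M, eps = eps, E = E, phi_e = phi_e, S_n = S_n, delta_n = delta_n,
      D_n = D_n, chi = chi, l_n = l_n)
}

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (mm, day, mM, Pa)\n")
  cat(sprintf("  growth:    nu_c = %g /day, delta_c = %g, phi_e = %g\n",
              object@nu_c, object@delta_c, object@phi_e))
  cat(sprintf("  mechanics: M = %g mm^-2 Pa day, E = %g Pa, eps = %g, chi = %g Pa\n",
              object@M, object@E, object@eps, object@chi))
  cat(sprintf("  oxygen:    n_s = %g mM, S_n = %g /day, delta_n = %g /day, D_n = %g mm^2/day, l_n = %g mm\n",
              object@n_s, object@S_n, object@delta_n, object@D_n, object@l_n))
  cat(sprintf("  chemotaxis: k_n = %g mm^2 mM^-1 day^-1\n", object@k_n))
})

## phi clipped into [0, 1 - eta] before constitutive evaluation; overshoot is a
## numerical artifact that must not produce infinities in f or its slope.
## Returns the clipped vector with the number of clipped entries as an
## attribute so callers can log saturation events.
clipPhi <- function(phi, eta = 1e-6) {
  hi <- 1 - eta
  nclip <- sum(phi < 0 | phi > hi)
  out <- pmin(pmax(phi, 0), hi)
  attr(out, "n_clipped") <- nclip
  out
}

#' Bulk pressure derivative f(phi) of the cell free energy
#'
#' The derivative of the bulk free energy per unit volume with respect to the
#' cell volume fraction,
#' \deqn{f(\phi) = E\,\phi^2 (\phi - \phi_e) / (1 - \phi),}
#' i.e. the homogeneous part of the excess pressure \eqn{\Sigma}. Cells attract
#' each other below the equilibrium fraction (\eqn{f < 0} for
#' \eqn{0 < \phi < \phi_e}), exert no net force at \eqn{\phi \in \{0,
#' \phi_e\}}, and repel with a pressure diverging as \eqn{\phi \to 1}.
#'
#' @param phi volume fraction(s) in \code{[0, 1)}.
#' @param params a [ModelParameters-class].
#' @return pressure(s) in Pa.
#' @examples
#' p <- modelParameters()
#' bulkPressureDerivative(c(0, 0.2, p@phi_e, 0.5), p)
#' @export
bulkPressureDerivative <- function(phi, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(phi < 0 | phi >= 1))
    stop("phi must lie in [0, 1): f(phi) is singular at phi = 1 and undefined for negative fractions")
  params@E * phi^2 * (phi - params@phi_e) / (1 - phi)
}

## d f / d phi, needed by the Newton linearization of the mixed system.
bulkPressureSlope <- function(phi, params) {
  E <- params@E; pe <- params@phi_e
  omp <- 1 - phi
  E * phi * ((2 * (phi - pe) + phi) * omp + phi * (phi - pe)) / omp^2
}

#' Degenerate motility coefficient K(phi)
#'
#' The mobility of the Darcy-like cell velocity \eqn{v_c = -K(\phi)\nabla
#' \Sigma},
#' \deqn{K(\phi) = (1 - \phi)^2 / M,}
#' the inverse of the interphase friction, vanishing at cell-contact
#' saturation \eqn{\phi = 1}.
#'
#' @param phi volume fraction(s) in \code{[0, 1]}.
#' @param params a [ModelParameters-class] (uses \code{M}).
#' @return mobility in mm^2 Pa^-1 day^-1.
#' @examples
#' motility(c(0, 0.5, 1), modelParameters(M = 2000))
#' @export
motility <- function(phi, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  (1 - phi)^2 / params@M
}

## Flux coefficient of the Sigma equation, c(phi) = phi * K(phi), and its
## derivative. Undershoot guard: max(phi, 0) inside the coefficient only.
sigmaFluxCoefficient <- function(phi, params, eta = 1e-6) {
  ph <- pmin(pmax(phi, 0), 1 - eta)
  ph * (1 - ph)^2 / params@M
}

sigmaFluxCoefficientSlope <- function(phi, params, eta = 1e-6) {
  ph <- pmin(pmax(phi, 0), 1 - eta)
  d <- ((1 - ph)^2 - 2 * ph * (1 - ph)) / params@M
  ## clipped regions contribute no sensitivity
  d[phi < 0 | phi > 1 - eta] <- 0
  d
}

#' Net tumor proliferation rate
#'
#' The volumetric mass source of the cell phase divided by the true density,
#' \deqn{\Gamma_c/\gamma = \nu_c\,\phi\,(n/n_s - \delta_c)\,(1 - \phi):}
#' growth proportional to the available cells, switching to hypoxic death
#' where oxygen falls below the fraction \eqn{\delta_c} of its physiological
#' level, and shut off by contact inhibition as \eqn{\phi \to 1}.
#'
#' @param phi volume fraction(s) in \code{[0, 1]}.
#' @param n oxygen concentration(s), mM, non-negative.
#' @param params a [ModelParameters-class].
#' @return rate(s) in 1/day.
#' @examples
#' p <- modelParameters(nu_c = 1, delta_c = 0.3)
#' netProliferation(0.5, p@n_s, p)     # well oxygenated: growth
#' netProliferation(0.5, 0, p)         # anoxia: death
#' @export
netProliferation <- function(phi, n, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(n < 0)) stop("oxygen concentration must be non-negative")
  params@nu_c * phi * (n / params@n_s - params@delta_c) * (1 - phi)
}

## d Gamma / d phi at fixed n.
netProliferationSlope <- function(phi, n, params) {
  params@nu_c * (n / params@n_s - params@delta_c) * (1 - 2 * phi)
}

#' Chemotactic mass flux of the cell phase
#'
#' The advective flux of cells drifting up the oxygen gradient along fiber
#' directions,
#' \deqn{J = k_n\,\phi\,\mathbf{T}\,\nabla n,}
#' whose negative divergence enters the tumor-phase equation. With
#' \eqn{\mathbf{T} = \mathbf{I}} this is the isotropic Keller-Segel flux; a
#' degenerate \eqn{\mathbf{T}} (e.g. \code{diag(3, 0, 0)}) confines the drift
#' to the fiber axis.
#'
#' @param phi volume fraction (scalar, or one per row of \code{grad_n}).
#' @param grad_n oxygen gradient, a 3-vector or an n x 3 matrix (mM/mm).
#' @param T_tensor symmetric 3x3 tensor with non-negative eigenvalues.
#' @param k_n chemotactic coefficient (mm^2 mM^-1 day^-1).
#' @return flux with the shape of \code{grad_n}.
#' @examples
#' chemotacticFlux(0.4, c(0.01, 0.01, 0), diag(c(3, 0, 0)), k_n = 100)
#' @export
chemotacticFlux <- function(phi, grad_n, T_tensor, k_n) {
  T_tensor <- as.matrix(T_tensor)
  if (!isTRUE(all.equal(T_tensor, t(T_tensor), tolerance = 1e-8)))
    stop("the preferential-direction tensor must be symmetric")
  ev <- eigen(T_tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("the preferential-direction tensor must have non-negative eigenvalues")
  if (is.matrix(grad_n)) {
    k_n * phi * grad_n %*% T_tensor
  } else {
    as.numeric(k_n * phi * (T_tensor %*% grad_n))
  }
}

#' Oxygen uptake rate from diffusivity and penetration length
#'
#' The consumption rate of oxygen by tumor cells follows from the diffusivity
#' and the distance a molecule travels before uptake:
#' \eqn{\delta_n = D_n / l_n^2}. With the literature values
#' \eqn{D_n \in [86.4, 156.5]} mm^2/day and \eqn{l_n = 0.1} mm this gives the
#' admissible range 8640-15650 /day.
#'
#' @param D_n oxygen diffusivity, mm^2/day, positive.
#' @param l_n oxygen penetration length, mm, positive.
#' @return uptake rate in 1/day.
#' @examples
#' deriveUptakeRate(86.4, 0.1)
#' deriveUptakeRate(156.5, 0.1)
#' @export
deriveUptakeRate <- function(D_n, l_n) {
  if (any(D_n <= 0) || any(l_n <= 0)) stop("D_n and l_n must be strictly positive")
  D_n / l_n^2
}

#' Interface coefficient from pressure scale and cell size
#'
#' One dimensionally consistent reconstruction of the diffuse-interface
#' coefficient from the interstitial fluid pressure scale \eqn{\chi} and the
#' cell-cell interaction distance (of the order of the cell size):
#' \deqn{\epsilon = \sqrt{\chi}\; \ell_{cell},}
#' so that \eqn{\epsilon^2 \Delta\phi} carries pressure units, consistent
#' with \eqn{f(\phi)} inside \eqn{\Sigma}. The package otherwise accepts
#' \code{eps} directly as a number (see [modelParameters()]).
#'
#' @param chi pressure scale, Pa, positive.
#' @param cell_size interaction distance, mm, positive.
#' @return epsilon in Pa^(1/2) mm.
#' @examples
#' deriveInterfaceCoefficient(900, 0.015)
#' @export
deriveInterfaceCoefficient <- function(chi, cell_size) {
  if (any(chi <= 0) || any(cell_size <= 0))
    stop("chi and cell_size must be strictly positive")
  sqrt(chi) * cell_size
}
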
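#' Prepore free energy
#'
#' Classical pore-nucleation free energy of a circular prepore of radius r in
#' a membrane under total lateral tension \eqn{\sigma_e + B}:
#' \deqn{U(r) = 2\pi r \Gamma - \pi(\sigma_e + B) r^2.}
#' The line term (edge tension \eqn{\Gamma}, energy per unit rim length)
#' resists expansion; the tension term drives it. `B` is the constant
#' electrostatic tension contributed by the membrane surface charge
#' (1.76 mN/m for the DOPG/DOPC system studied here).
#'
#' @param r pore radius (m); non-negative.
#' @param Gamma pore-edge tension (N); use [pN()] at the boundary.
#' @param sigma_e applied lateral tension (N/m).
#' @param B electrostatic tension component (N/m), default 1.76e-3.
#' @return Free energy (J).
#' @examples
#' pore_free_energy(0.5e-9, Gamma = pN(9.6), sigma_e = mN_per_m(8))
#' @seealso [critical_radius()], [energy_barrier()], [rupture_rate()]
#' @export
pore_free_energy <- function(r, Gamma, sigma_e, B = 1.76e-3) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("pore radius r must be finite and non-negative", call. = FALSE)
  }
  check_pore_params(Gamma, sigma_e, B)
  2 * pi * r * Gamma - pi * (sigma_e + B) * r^2
}

#' Critical pore radius
#'
#' The maximizer of the prepore free energy, \eqn{r_c = \Gamma/(\sigma_e + B)}.
#' Prepores below `r_c` reseal; prepores that reach it expand without bound
#' and the vesicle ruptures.
#'
#' @inheritParams pore_free_energy
#' @return Critical radius (m).
#' @export
critical_radius <- function(Gamma, sigma_e, B = 1.76e-3) {
  check_pore_params(Gamma, sigma_e, B, need_tension = TRUE)
  if (any(Gamma <= 0)) {
    stop("critical radius requires strictly positive edge tension Gamma",
         call. = FALSE)
  }
  Gamma / (sigma_e + B)
}

#' Pore nucleation energy barrier
#'
#' The prepore free energy evaluated at the critical radius,
#' \deqn{U_b = \frac{\pi \Gamma^2}{\sigma_e + B},}
#' the activation barrier separating the intact membrane from irreversible
#' rupture.
#'
#' @inheritParams pore_free_energy
#' @param constants optional [membrane_constants()]; when supplied the barrier
#'   is also returned in units of \eqn{k_B T} as attribute `"kBT"`.
#' @return Barrier height (J), with attribute `"kBT"` if `constants` given.
#' @examples
#' ub <- energy_barrier(pN(9.6), mN_per_m(8), constants = membrane_constants())
#' attr(ub, "kBT") # ~7.2
#' @export
energy_barrier <- function(Gamma, sigma_e, B = 1.76e-3, constants = NULL) {
  check_pore_params(Gamma, sigma_e, B, need_tension = TRUE)
  ub <- pi * Gamma^2 / (sigma_e + B)
  if (!is.null(constants)) {
    constants <- as_membrane_constants(constants)
    attr(ub, "kBT") <- ub / (constants$k_B * constants$T)
  }
  ub
}

#' Arrhenius rupture rate constant
#'
#' Thermally activated crossing of the nucleation barrier gives the rupture
#' rate
#' \deqn{k_r = A \exp\!\left[-\frac{\pi\Gamma^2}{(\sigma_e + B)\,k_B T}\right],}
#' strictly increasing in applied tension and temperature, strictly
#' decreasing in edge tension. `A` is the attempt-frequency prefactor.
#'
#' @inheritParams pore_free_energy
#' @param A frequency factor (1/s); strictly positive.
#' @param constants a [membrane_constants()] object (supplies `k_B`, `T`).
#' @return Rate constant (1/s).
#' @examples
#' rupture_rate(A = 300, Gamma = pN(9.6), sigma_e = mN_per_m(8)) # ~0.22 /s
#' @export
rupture_rate <- function(A, Gamma, sigma_e, B = 1.76e-3,
                         constants = membrane_constants()) {
  constants <- as_membrane_constants(constants)
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("frequency factor A must be finite and strictly positive",
         call. = FALSE)
  }
  check_pore_params(Gamma, sigma_e, B, need_tension = TRUE)
  A * exp(-pi * Gamma^2 / ((sigma_e + B) * constants$k_B * constants$T))
}

#' Biphasic edge tension versus peptide mole fraction
#'
#' Quadratic model of the pore-edge tension as a function of the mole
#' fraction \eqn{\phi} of a channel-forming peptide (gramicidin A) in the
#' bilayer:
#' \deqn{\Gamma(\phi) = \Gamma_0 + a\phi - b\phi^2.}
#' \eqn{\Gamma_0} is the edge tension of the peptide-free bilayer. The signs
#' of `a` and `b` are deliberately unconstrained: they are empirical
#' coefficients recovered by [fit_biphasic()], and a non-monotonic (biphasic)
#' dependence corresponds to an interior vertex at \eqn{\phi^* = a/(2b)}.
#'
#' @param phi peptide mole fraction, in \[0, 1\].
#' @param Gamma0 edge tension at `phi = 0` (N); strictly positive.
#' @param a linear coefficient (N per unit mole fraction).
#' @param b quadratic coefficient (N per unit mole fraction squared); note
#'   the model term is `-b * phi^2`.
#' @return Edge tension (N).
#' @export
biphasic_edge_tension <- function(phi, Gamma0, a, b) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    stop("mole fraction phi must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(Gamma0)) || any(Gamma0 <= 0)) {
    stop("Gamma0 must be finite and strictly positive", call. = FALSE)
  }
  Gamma0 + a * phi - b * phi^2
}

#' Rupture rate as a function of peptide content
#'
#' Composition of [biphasic_edge_tension()] with [rupture_rate()]: the rate
#' constant at peptide mole fraction `phi` under tension `sigma_e`.
#'
#' @inheritParams biphasic_edge_tension
#' @inheritParams rupture_rate
#' @return Rate constant (1/s).
#' @export
biphasic_rupture_rate <- function(phi, Gamma0, a, b, A, sigma_e, B = 1.76e-3,
                                  constants = membrane_constants()) {
  rupture_rate(A = A, Gamma = biphasic_edge_tension(phi, Gamma0, a, b),
               sigma_e = sigma_e, B = B, constants = constants)
}

#' Helfrich bending energy density
#'
#' Elastic energy per unit area of a membrane bent to local curvature `C`
#' when its spontaneous curvature is `C0`:
#' \deqn{E_{bend} = \tfrac{1}{2}\kappa (C - C_0)^2,}
#' minimized (zero) where the actual curvature matches the spontaneous one.
#' Peptide inclusions that raise `C0` toward the rim curvature of a toroidal
#' pore lower the bending cost of forming one.
#'
#' @param kappa bending rigidity (J); strictly positive.
#' @param C actual local curvature (1/m).
#' @param C0 spontaneous curvature (1/m); default 0.
#' @return Energy per unit area (J/m^2).
#' @export
bending_energy <- function(kappa, C, C0 = 0) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("bending rigidity kappa must be finite and strictly positive",
         call. = FALSE)
  }
  0.5 * kappa * (C - C0)^2
}

check_pore_params <- function(Gamma, sigma_e, B, need_tension = FALSE) {
  if (any(!is.finite(Gamma)) || any(Gamma < 0)) {
    stop("edge tension Gamma must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(sigma_e)) || any(sigma_e < 0)) {
    stop("lateral tension sigma_e must be finite and non-negative",
         call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B < 0)) {
    stop("electrostatic tension B must be finite and non-negative",
         call. = FALSE)
  }
  if (need_tension && any(sigma_e + B <= 0)) {
    stop("total tension sigma_e + B must be strictly positive", call. = FALSE)
  }
  invisible(NULL)
}
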
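#' Transmembrane voltage induced on a spherical vesicle
#'
#' For a thin spherical dielectric shell in a uniform quasi-static field the
#' induced potential difference across the membrane is
#' \deqn{V_m = 1.5 \, R \, E \, |\cos\theta|,}
#' the classical Schwan result, maximal at the vesicle poles (\eqn{\theta = 0}).
#' The rupture analysis throughout this package uses the pole value, where
#' poration initiates first.
#'
#' @param R vesicle radius (m); strictly positive.
#' @param E applied field magnitude (V/m); non-negative.
#' @param theta angle between the field and the bilayer normal (radians);
#'   default 0 (pole).
#' @return Transmembrane voltage (V).
#' @examples
#' transmembrane_voltage(um(10), V_per_cm(553)) # 0.83 V
#' @seealso [tension_from_voltage()], [tension_from_field()]
#' @export
transmembrane_voltage <- function(R, E, theta = 0) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("vesicle radius R must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(E)) || any(E < 0)) {
    stop("field magnitude E must be finite and non-negative", call. = FALSE)
  }
  1.5 * R * E * abs(cos(theta))
}

#' Lateral electric tension from transmembrane voltage
#'
#' The Maxwell stress of the accumulated interfacial charge compresses the
#' membrane and appears as an in-plane tension
#' \deqn{\sigma_e = \varepsilon_m \varepsilon_0 \frac{h}{2 h_e^2} V_m^2,}
#' quadratic in the voltage.
#'
#' @param V_m transmembrane voltage (V); non-negative.
#' @param constants a [membrane_constants()] object.
#' @return Lateral tension (N/m); multiply by [to_mN_per_m()] for reporting.
#' @examples
#' to_mN_per_m(tension_from_voltage(0.83)) # ~7 mN/m
#' @export
tension_from_voltage <- function(V_m, constants = membrane_constants()) {
  constants <- as_membrane_constants(constants)
  if (any(!is.finite(V_m)) || any(V_m < 0)) {
    stop("V_m must be finite and non-negative", call. = FALSE)
  }
  constants$epsilon_m * constants$epsilon_0 *
    constants$h / (2 * constants$h_e^2) * V_m^2
}

#' Lateral electric tension from applied field and vesicle radius
#'
#' Composes [transmembrane_voltage()] at the pole with
#' [tension_from_voltage()], giving \eqn{\sigma_e = c\, R^2 E^2} with
#' \eqn{c = 2.25\,\varepsilon_m \varepsilon_0 h / (2 h_e^2)}. With the default
#' constants \eqn{c} is 22.86 mN m^-1 per m^2 (V/m)^2, the conventional
#' coefficient for this geometry.
#'
#' @inheritParams transmembrane_voltage
#' @inheritParams tension_from_voltage
#' @return Lateral tension (N/m).
#' @examples
#' to_mN_per_m(tension_from_field(um(10), V_per_cm(553))) # ~7 mN/m
#' @export
tension_from_field <- function(R, E, constants = membrane_constants()) {
  tension_from_voltage(transmembrane_voltage(R, E, theta = 0), constants)
}

#' Field strength required to impose a target tension
#'
#' Closed-form inverse of [tension_from_field()]: given a measured vesicle
#' radius and a target lateral tension, returns the field to apply. This
#' mirrors the experimental protocol, where each vesicle's diameter is
#' measured first and the field is then set so every vesicle experiences the
#' same tension.
#'
#' @param R vesicle radius (m); strictly positive.
#' @param sigma_target target lateral tension (N/m); strictly positive.
#' @inheritParams tension_from_voltage
#' @return Field magnitude (V/m).
#' @examples
#' field_for_target_tension(um(10), mN_per_m(7)) / 100 # ~553 V/cm
#' @export
field_for_target_tension <- function(R, sigma_target,
                                     constants = membrane_constants()) {
  constants <- as_membrane_constants(constants)
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("vesicle radius R must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(sigma_target)) || any(sigma_target <= 0)) {
    stop("target tension must be finite and strictly positive", call. = FALSE)
  }
  prefactor <- constants$epsilon_m * constants$epsilon_0 *
    constants$h / (2 * constants$h_e^2)
  sqrt(sigma_target / prefactor) / (1.5 * R)
}
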
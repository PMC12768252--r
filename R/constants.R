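#' Physical constants of the bilayer and its environment
#'
#' Bundles the membrane and environmental constants that enter the
#' electromechanical tension map and the Arrhenius rupture rate. The defaults
#' describe a DOPG/DOPC bilayer at 25 degrees C: relative permittivity 4.5,
#' thickness 4 nm, dielectric thickness 2.8 nm.
#'
#' `epsilon_0` defaults to 8.85e-12 F/m rather than the full CODATA value:
#' with the default geometry this reproduces the conventional tension
#' coefficient 22.86 mN m^-1 m^-2 (V/m)^-2 exactly at two decimals
#' (CODATA 8.8541878e-12 gives 22.87). All fields are configurable.
#'
#' @param epsilon_m relative membrane permittivity (dimensionless).
#' @param epsilon_0 vacuum permittivity (F/m).
#' @param h membrane thickness (m).
#' @param h_e membrane dielectric thickness (m); must not exceed `h`.
#' @param T absolute temperature (K).
#' @param k_B Boltzmann constant (J/K).
#'
#' @return An object of class `"membrane_constants"`: a named list with the
#'   six fields above.
#' @examples
#' mc <- membrane_constants()
#' tension_from_voltage(0.83, mc) # ~7e-3 N/m
#' @export
membrane_constants <- function(epsilon_m = 4.5, epsilon_0 = 8.85e-12,
                               h = 4e-9, h_e = 2.8e-9,
                               T = 298.15, k_B = 1.380649e-23) {
  vals <- c(epsilon_m = epsilon_m, epsilon_0 = epsilon_0, h = h,
            h_e = h_e, T = T, k_B = k_B)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all membrane constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (h_e > h) stop("dielectric thickness h_e cannot exceed thickness h",
                    call. = FALSE)
  structure(as.list(vals), class = "membrane_constants")
}

#' @export
print.membrane_constants <- function(x, ...) {
  cat("Membrane constants:\n")
  cat(sprintf("  epsilon_m = %g, epsilon_0 = %g F/m\n", x$epsilon_m, x$epsilon_0))
  cat(sprintf("  h = %g nm, h_e = %g nm\n", x$h * 1e9, x$h_e * 1e9))
  cat(sprintf("  T = %g K, k_B = %g J/K\n", x$T, x$k_B))
  invisible(x)
}

as_membrane_constants <- function(x) {
  if (inherits(x, "membrane_constants")) return(x)
  if (is.null(x)) return(membrane_constants())
  do.call(membrane_constants, as.list(x))
}

#' Unit helpers for the I/O boundary
#'
#' All computation in this package is in SI units (m, V/m, N/m, N, J). The
#' experimental literature quotes radii in micrometres, fields in V/cm,
#' tensions in mN/m and edge tensions in pN; these helpers convert such
#' boundary values to SI (and back, for reporting).
#'
#' @param x numeric vector in the unit named by the function.
#' @return Numeric vector in SI units (or, for the `to_*` converters, in the
#'   named reporting unit).
#' @examples
#' transmembrane_voltage(um(10), V_per_cm(553)) # 0.83 V
#' @name units
NULL

#' @rdname units
#' @export
um <- function(x) x * 1e-6

#' @rdname units
#' @export
V_per_cm <- function(x) x * 100

#' @rdname units
#' @export
mN_per_m <- function(x) x * 1e-3

#' @rdname units
#' @export
pN <- function(x) x * 1e-12

#' @rdname units
#' @export
to_mN_per_m <- function(x) x * 1e3

#' @rdname units
#' @export
to_pN <- function(x) x * 1e12
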
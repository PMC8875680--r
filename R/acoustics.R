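# Closed-form material acoustics: Young's modulus from stress-strain data,
# speed of sound and acoustic impedance of a porous solid, tissue impedance
# mismatch, pore-density / scattering attenuation, and the power-law
# attenuation prediction linking alpha to Y/rho.

#' Young's modulus from stress-strain data
#'
#' Least-squares slope of the stress-strain line, `Y = stress / strain` in
#' the linear-elastic regime. The caller is responsible for restricting the
#' data to the elastic region (e.g. the initial portion of a compression
#' test's travel/load curve); no automatic window selection is performed.
#'
#' @param stress numeric vector, Pa.
#' @param strain numeric vector, dimensionless, same length as `stress`.
#' @return Young's modulus in Pa (slope of the least-squares line).
#' @examples
#' young_modulus(c(0, 1e5), c(0, 0.01))       # 1e7 Pa
#' @export
young_modulus <- function(stress, strain) {
  if (!is.numeric(stress) || !is.numeric(strain))
    abort_invalid("stress and strain must be numeric vectors")
  if (length(stress) != length(strain))
    abort_invalid("stress and strain must have the same length")
  if (length(stress) < 2L)
    abort_invalid("at least 2 stress-strain points are required")
  if (anyNA(stress) || anyNA(strain))
    abort_invalid("stress/strain must not contain missing values")
  sx <- strain - mean(strain)
  if (sum(sx^2) == 0)
    abort_degenerate("strain values are all identical; slope is undefined")
  sum(sx * (stress - mean(stress))) / sum(sx^2)
}

#' Speed of sound in a solid
#'
#' `v = sqrt(Y / rho)`: longitudinal bar speed from Young's modulus and bulk
#' density. For the highly porous aerogels this package targets, v is of
#' order 10-100 m/s, far below typical solids.
#'
#' @param Y Young's modulus, Pa. May also be a `material_properties` object.
#' @param rho bulk density, kg/m^3 (ignored when `Y` is a
#'   `material_properties` object).
#' @return speed of sound, m/s.
#' @export
sound_speed <- function(Y, rho) {
  if (inherits(Y, "material_properties")) {
    rho <- Y$rho; Y <- Y$Y
  }
  if (!all(is.finite(Y)) || !all(is.finite(rho)) || any(Y <= 0) || any(rho <= 0))
    abort_invalid("Y and rho must be positive and finite")
  sqrt(Y / rho)
}

#' Acoustic impedance of a solid
#'
#' `Z = rho * v = sqrt(rho * Y)`, in rayl (kg m^-2 s^-1).
#'
#' @inheritParams sound_speed
#' @return acoustic impedance, rayl.
#' @export
acoustic_impedance <- function(Y, rho) {
  if (inherits(Y, "material_properties")) {
    rho <- Y$rho; Y <- Y$Y
  }
  if (!all(is.finite(Y)) || !all(is.finite(rho)) || any(Y <= 0) || any(rho <= 0))
    abort_invalid("Y and rho must be positive and finite")
  sqrt(rho * Y)
}

#' Impedance mismatch between tissue and implant
#'
#' Percentage difference `(Z_tissue - Z_implant) / Z_tissue * 100`. Large
#' mismatches (>90% for aerogels against soft tissue at ~1.6 Mrayl) drive
#' the strong boundary echo and posterior shadowing seen in B-mode images.
#'
#' @param Z_tissue tissue acoustic impedance, rayl (> 0).
#' @param Z_implant implant acoustic impedance, rayl (>= 0); vectorized.
#' @return mismatch in percent; 100 iff `Z_implant == 0`, 0 for matched media.
#' @export
impedance_mismatch <- function(Z_tissue, Z_implant) {
  if (!is_scalar_num(Z_tissue) || Z_tissue <= 0)
    abort_invalid("Z_tissue must be a positive scalar")
  if (!is.numeric(Z_implant) || any(!is.finite(Z_implant)) || any(Z_implant < 0))
    abort_invalid("Z_implant must be non-negative and finite")
  (Z_tissue - Z_implant) / Z_tissue * 100
}

#' Pore density of a porous solid
#'
#' `gamma = 4 * porosity / (pi * phi^2)`: areal number density of pores of
#' diameter `phi` at a given volume porosity. Strictly decreasing in `phi`
#' at fixed porosity (halving the pore diameter quadruples gamma).
#'
#' @param porosity volume fraction of pores, in (0, 1].
#' @param phi pore diameter, m (> 0).
#' @return pore density, m^-2.
#' @export
pore_density <- function(porosity, phi) {
  if (!is.numeric(porosity) || any(!is.finite(porosity)) ||
      any(porosity <= 0) || any(porosity > 1))
    abort_invalid("porosity must lie in (0, 1]")
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi <= 0))
    abort_invalid("phi must be positive")
  4 * porosity / (pi * phi^2)
}

#' Scattering attenuation from pore density
#'
#' `alpha = gamma * s / 2` where `s` is the scattering cross-section of a
#' single pore. Composed with [pore_density()], attenuation is inversely
#' proportional to the squared pore diameter. Units follow the inputs
#' (per-m if gamma is m^-2 and s is m^2); any per-cm conversion is applied
#' explicitly at the reporting layer.
#'
#' @param gamma pore density, m^-2 (>= 0).
#' @param scatter_xsec scattering cross-section per pore, m^2 (>= 0).
#' @return attenuation, nepers per unit length of the inputs.
#' @export
scattering_attenuation <- function(gamma, scatter_xsec) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma < 0))
    abort_invalid("gamma must be non-negative")
  if (!is.numeric(scatter_xsec) || any(!is.finite(scatter_xsec)) ||
      any(scatter_xsec < 0))
    abort_invalid("scatter_xsec must be non-negative")
  gamma * scatter_xsec / 2
}

#' Predicted attenuation from stiffness, density and wavelength
#'
#' `alpha = (alpha0 / lambda^n) * (Y / rho)^(n/2)`, obtained by eliminating
#' frequency between the power law `alpha = alpha0 * f^n` and the dispersion
#' relation `sqrt(Y/rho) = lambda * f`. For `n = 2` the prediction is
#' exactly linear in `Y / rho`.
#'
#' @param alpha0 attenuation prefactor (same units as the returned alpha at
#'   unit frequency).
#' @param lam wavelength (> 0), same length unit as used in `alpha0`.
#' @param n power-law exponent, dimensionless.
#' @param Y Young's modulus, Pa (>= 0).
#' @param rho bulk density, kg/m^3 (> 0).
#' @return predicted attenuation.
#' @export
predicted_attenuation <- function(alpha0, lam, n, Y, rho) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0))
    abort_invalid("lam must be positive")
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0))
    abort_invalid("rho must be positive")
  if (!is.numeric(Y) || any(!is.finite(Y)) || any(Y < 0))
    abort_invalid("Y must be non-negative")
  (alpha0 / lam^n) * (Y / rho)^(n / 2)
}
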
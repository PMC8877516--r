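#' Physical constants (CODATA 2018) used throughout the package
#'
#' All internal electrostatics are done in the "simulation" unit system of
#' continuum solvers: length in Angstrom, charge in elementary charges e,
#' potential in kT/e and force in kT/Angstrom. The two derived quantities
#' that carry the unit conversions are the Coulomb constant in kT*A/e^2
#' (so that phi = coulomb_const(T) * q / (eps * r) in a uniform dielectric)
#' and the Debye screening length in Angstrom.
#'
#' @name pb-constants
#' @keywords internal
NULL

.codata <- list(
  e_charge  = 1.602176634e-19,   # C
  k_boltz   = 1.380649e-23,      # J/K
  eps0      = 8.8541878128e-12,  # F/m
  avogadro  = 6.02214076e23      # 1/mol
)

#' Coulomb constant in kT*Angstrom/e^2
#'
#' @param temperature temperature in Kelvin.
#' @return scalar: `phi [kT/e] = coulomb_const(T) * q [e] / (eps * r [A])`.
#' @export
#' @examples
#' coulomb_const(298.15)  # ~560.5
coulomb_const <- function(temperature = 298.15) {
  stopifnot(temperature > 0)
  with(.codata,
       e_charge^2 / (4 * pi * eps0 * k_boltz * temperature * 1e-10))
}

#' Debye screening length in Angstrom
#'
#' Screening length of a 1:1 electrolyte of the given ionic strength in a
#' uniform dielectric. Potentials of a point charge decay as
#' exp(-r/lambda_D)/r.
#'
#' @param ionic_strength mol/L.
#' @param eps_out solvent relative dielectric constant.
#' @param temperature Kelvin.
#' @return length in Angstrom; `Inf` when `ionic_strength` is 0.
#' @export
#' @examples
#' debye_length(0.15)  # ~7.9 A in water at 298.15 K
debye_length <- function(ionic_strength, eps_out = 80, temperature = 298.15) {
  stopifnot(ionic_strength >= 0, eps_out > 0, temperature > 0)
  if (ionic_strength == 0) return(Inf)
  lam2_m2 <- with(.codata,
    eps_out * eps0 * k_boltz * temperature /
      (2 * avogadro * e_charge^2 * ionic_strength * 1000))
  sqrt(lam2_m2) * 1e10
}
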
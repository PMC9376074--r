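# Unit system: length in Angstrom, energy in kcal/mol, mass in Da.
# The derived DMD time unit is sqrt(Da * A^2 / (kcal/mol)) ~= 48.9 fs,
# presented to users as ~50 fs; temperatures in Kelvin, forces in pN.

.AVOGADRO <- 6.02214076e23
.KCAL_J <- 4184

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCALMOL <- 8.31446261815324 / .KCAL_J  # R[J/mol/K] / (J/kcal)

#' The DMD time unit in femtoseconds
#'
#' One internal time unit is `sqrt(Da * A^2 / (kcal/mol))`, approximately
#' 48.9 fs (reported as ~50 fs per simulation step).
#' @return scalar, fs per time unit
#' @export
dmd_time_unit_fs <- function() {
  sqrt(1e-3 * 1e-20 / .KCAL_J) * 1e15
}

#' Convert nanoseconds to internal time units (and back)
#' @param ns,tu times in nanoseconds / internal units
#' @return converted times
#' @export
ns_to_tu <- function(ns) ns * 1e6 / dmd_time_unit_fs()

#' @rdname ns_to_tu
#' @export
tu_to_ns <- function(tu) tu * dmd_time_unit_fs() / 1e6

#' Convert a force in piconewtons to kcal/mol/Angstrom
#'
#' 1 kcal/mol/A = 69.48 pN; the conversion is computed from CODATA constants.
#' @param pN force in piconewtons
#' @return force in kcal/mol/A
#' @export
pn_to_kcalmolA <- function(pN) pN / pn_per_kcalmolA()

#' @rdname pn_to_kcalmolA
#' @export
pn_per_kcalmolA <- function() .KCAL_J / .AVOGADRO / 1e-10 * 1e12

#' Thermal energy kT in kcal/mol
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
kT_kcalmol <- function(temperature) KB_KCALMOL * temperature
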
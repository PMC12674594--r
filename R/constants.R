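## Physical constants pinned package-wide. Internal units are bohr / hartree
## everywhere; kcal/mol and kJ/mol appear only at reporting boundaries.

#' Physical constants used throughout the package
#'
#' All internal computation is carried out in atomic units (bohr, hartree).
#' Unit conversions happen only at reporting boundaries, with the constants
#' pinned here as the single source of truth.
#'
#' @format A list with elements:
#' \describe{
#'   \item{hartree_to_kcalmol}{1 Eh in kcal/mol (627.5094740631)}
#'   \item{hartree_to_kjmol}{1 Eh in kJ/mol (2625.4996394799)}
#'   \item{bohr_to_angstrom}{1 bohr in Angstrom}
#'   \item{proton_mass_au}{proton mass in electron masses (CODATA)}
#'   \item{gas_constant_kcal}{R in kcal mol^-1 K^-1}
#'   \item{default_temperature}{standard-state temperature in K}
#' }
#' @export
neodh_constants <- list(
  hartree_to_kcalmol = 627.5094740631,
  hartree_to_kjmol   = 2625.4996394799,
  bohr_to_angstrom   = 0.529177210903,
  proton_mass_au     = 1836.15267343,
  gas_constant_kcal  = 1.987204259e-3,
  default_temperature = 298.15
)

angstrom_to_bohr <- function(x) x / neodh_constants$bohr_to_angstrom
bohr_to_angstrom <- function(x) x * neodh_constants$bohr_to_angstrom
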
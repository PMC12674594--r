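## Proton-affinity thermochemistry.
##
## The proton affinity is the negative protonation enthalpy.  With the
## ideal-gas translational term of the vanishing free proton
## (Delta E_trans = -3/2 RT) and negligible rotational change, the enthalpy
## route `PA = -Delta H = -Delta E + RT` becomes
##   single-component:  PA(A) = -Delta E_elec - Delta E_vib + 5/2 RT
##   multicomponent:    PA(A) = E_A - E_AH+ + 5/2 RT
## where the NEO energy of the protonated species includes the anharmonic
## zero-point energy of the quantum proton implicitly, and zero-point
## contributions of the classical nuclei predominantly cancel between A and
## AH+ (so the NEO route adds no classical-vibration correction).

#' Thermochemistry constants
#' @export
thermo_constants <- function() {
  list(R = neodh_constants$gas_constant_kcal,
       T_default = neodh_constants$default_temperature)
}

#' Proton affinity, multicomponent route
#'
#' @param E_A single-component total energy of the unprotonated molecule (Eh)
#' @param E_AH_neo multicomponent total energy of the protonated molecule
#'   with the added proton quantized (Eh)
#' @param T temperature in K
#' @return proton affinity in kcal/mol
#' @export
proton_affinity_neo <- function(E_A, E_AH_neo,
                                T = neodh_constants$default_temperature) {
  (E_A - E_AH_neo) * neodh_constants$hartree_to_kcalmol +
    2.5 * neodh_constants$gas_constant_kcal * T
}

#' Proton affinity, single-component route
#'
#' @param E_A,E_AH electronic energies of A and AH+ (Eh)
#' @param dE_vib change of the harmonic vibrational energy (including
#'   zero-point energy) upon protonation, kcal/mol, from an external
#'   frequency calculation
#' @param T temperature in K
#' @return proton affinity in kcal/mol
#' @export
proton_affinity_sc <- function(E_A, E_AH, dE_vib = 0,
                               T = neodh_constants$default_temperature) {
  -(E_AH - E_A) * neodh_constants$hartree_to_kcalmol - dE_vib +
    2.5 * neodh_constants$gas_constant_kcal * T
}

#' Load an embedded proton-affinity reference table
#'
#' "PA21" holds the 21-molecule parametrization set (11 carboxylates, 6
#' amines, 3 aromatics, 1 inorganic); "test" the 9-molecule evaluation set of
#' titratable molecules.  Experimental values in kcal/mol.
#'
#' @param name "PA21" or "test"
#' @return data.frame with columns label, formula, class, pa_exp_kcal
#' @export
load_dataset <- function(name = c("PA21", "test")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   if (name == "PA21") "pa21.csv" else "pa_testset.csv",
                   package = "neodh", mustWork = TRUE)
  d <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(!anyDuplicated(d$label), all(d$pa_exp_kcal > 0))
  d
}

#' Score computed proton affinities against a reference table
#'
#' @param entries data.frame as returned by [load_dataset()]
#' @param computed named numeric vector of computed PAs (kcal/mol), names
#'   matching the dataset labels
#' @param route annotation ("neo" or "single-component")
#' @return list with `results` (per-entry table including unsigned errors)
#'   and `summary` (MUE, RMSD, median UE, min, max)
#' @export
evaluate_dataset <- function(entries, computed, route = "neo") {
  miss <- setdiff(entries$label, names(computed))
  if (length(miss) > 0) {
    stop("computed PAs missing for labels: ", paste(miss, collapse = ", "))
  }
  pa <- as.numeric(computed[as.character(entries$label)])
  ue <- abs(pa - entries$pa_exp_kcal)
  results <- data.frame(label = entries$label, class = entries$class,
                        pa_exp = entries$pa_exp_kcal, pa_calc = pa,
                        ue = ue, route = route,
                        stringsAsFactors = FALSE)
  list(results = results, summary = pa_error_summary(ue))
}

pa_error_summary <- function(ue) {
  list(MUE = mean(ue), RMSD = sqrt(mean(ue^2)), median = stats::median(ue),
       min = min(ue), max = max(ue), n = length(ue))
}
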
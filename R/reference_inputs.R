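## Reference inputs for the small-molecule proton-affinity reproductions.
##
## Geometry optimization and harmonic frequencies are not features of this
## package; they were carried out once with the package's own SCF engine
## (B3LYP/synTZ, numerical gradients and finite-difference Hessians; see
## inst/scripts/make_reference_inputs.R) and their outputs are shipped as
## plain-text inputs: XYZ geometries and a table of harmonic vibrational
## energy changes.  The single-point energies entering the proton affinities
## are always recomputed from these inputs at run time.

#' Load a shipped reference geometry
#' @param name one of "nh3", "nh4", "no2", "hono"
#' @return a `QuantumMolecule`
#' @export
reference_geometry <- function(name = c("nh3", "nh4", "no2", "hono")) {
  name <- match.arg(name)
  f <- system.file("extdata", "geometries", paste0(name, ".xyz"),
                   package = "neodh", mustWork = TRUE)
  charge <- c(nh3 = 0L, nh4 = 1L, no2 = -1L, hono = 0L)[[name]]
  parse_xyz(readLines(f), charge = charge)
}

#' Load the shipped harmonic vibrational-energy changes
#' @return data.frame with reaction labels and dE_vib (kcal/mol) upon
#'   protonation at 298.15 K
#' @export
reference_vibrational_table <- function() {
  f <- system.file("extdata", "reference_vibrations.csv", package = "neodh",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
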
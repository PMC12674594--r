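## Single-component (electrons only) restricted Kohn-Sham / double-hybrid
## driver.  Produces an EnergyBreakdown whose slots are the unweighted energy
## components, so that every functional assembly is pure arithmetic over it.

new_energy_breakdown <- function(...) {
  structure(list(...), class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("EnergyBreakdown (Eh):\n")
  for (nm in setdiff(names(x), c("meta"))) {
    if (is.numeric(x[[nm]])) cat(sprintf("  %-14s %18.10f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Single-component SCF (+ optional MP2) calculation
#'
#' Runs a restricted closed-shell Kohn-Sham (or Hartree-Fock) calculation
#' and, for double-hybrid functionals, the spin-resolved MP2 correction on
#' the converged orbitals.
#'
#' @param mol a `QuantumMolecule` with no quantum protons
#' @param basis a `BasisConfiguration`
#' @param functional registry name or `FunctionalParams`
#' @param settings an `SCFSettings`
#' @param grid_level quadrature grid level
#' @param frozen_core "auto" or "none"
#' @param verbose print iteration log
#' @return list with `energy` (assembled total), `breakdown`, `scf` (orbital
#'   data), `functional`
#' @export
run_rks <- function(mol, basis = basis_configuration(), functional = "b3lyp",
                    settings = scf_settings(), grid_level = 3,
                    frozen_core = "auto", D0 = NULL, verbose = FALSE) {
  if (nrow(mol$quantum_protons) > 0) {
    stop("run_rks is single-component; use run_neo_scf for quantum protons")
  }
  fp <- if (inherits(functional, "FunctionalParams")) functional else
    get_functional(functional)
  if (mol$n_electrons %% 2L != 0L) {
    stop("open-shell electronic references are not supported")
  }
  need_grid <- length(fp$xc_scf) > 0
  bundle <- build_integrals(mol, basis, grid_level = grid_level,
                            two_electron = "conventional",
                            with_grid = need_grid)
  res <- rks_from_bundle(bundle, fp, settings, frozen_core, verbose, D0 = D0)
  res
}

## core driver over a prepared bundle (shared with the NEO electronic step)
rks_from_bundle <- function(bundle, fp, settings = scf_settings(),
                            frozen_core = "auto", verbose = FALSE,
                            D0 = NULL) {
  mol <- bundle$mol
  nelec <- mol$n_electrons
  nocc <- nelec %/% 2L
  h <- bundle$T - bundle$V
  if (is.null(D0)) {
    bdef <- resolve_electronic_basis(bundle$basis, unique(mol$symbols))
    D0 <- tryCatch(
      sad_guess(mol, bdef, bundle$shells_e, bundle$S, nelec),
      error = function(e) NULL)
  }
  ints <- list(S = bundle$S, h = h, eri = bundle$eri_ee,
               phi = bundle$phi_e, w = bundle$grid$weights)
  scf <- species_scf(ints, occ = rep(2, nocc), exchange = "closed_shell",
                     a_ex = fp$a_ex, xc_weights = fp$xc_scf,
                     settings = settings, D0 = D0, verbose = verbose)
  if (!scf$converged) {
    stop("SCF failed to converge in ", settings$max_iter,
         " iterations (last |dE| = ",
         format(abs(utils::tail(scf$log$dE, 1)), digits = 3), ")")
  }
  enn <- nuclear_repulsion(mol)
  bd <- new_energy_breakdown(
    E_ext_ref = scf$E1 + scf$EJ + enn,
    E_ex_hf = scf$EKfull,
    E_xc_scf = scf$Exc,
    E_disp = 0
  )
  dens <- scf$dens
  if (fp$family != "hybrid") {
    if (is.null(dens)) {
      dens <- grid_density(bundle$phi_e, scf$D)
    }
    bd$E_ex_dft <- xc_energy_only(bundle$grid$weights, dens, fp$ex_dft)
    bd$E_ec_dft <- xc_energy_only(bundle$grid$weights, dens, fp$ec_dft)
    nfr <- frozen_core_count(mol, frozen_core)
    mp2 <- electronic_mp2(scf$C, scf$eps, nocc, bundle$eri_ee, frozen = nfr)
    bd$E_ec_mp2_os <- mp2$E_os
    bd$E_ec_mp2_ss <- mp2$E_ss
  }
  bd$meta <- list(functional = fp$name, nbf = bundle$n_e,
                  n_iter = nrow(scf$log), converged = scf$converged)
  list(energy = assemble_energy(bd, fp), breakdown = bd, scf = scf,
       functional = fp, bundle_info = list(n_e = bundle$n_e))
}
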
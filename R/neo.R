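## Coupled electron-proton Kohn-Sham SCF (the NEO method).
##
## Two Fock operators are iterated to joint self-consistency: the electronic
## one carries kinetic energy, attraction to the classical nuclei, electronic
## Coulomb/exchange-correlation, attraction to the protonic density, and the
## (b_epc-scaled) electron-side epc-17.2 potential; the protonic one carries
## the mass-scaled kinetic energy, *repulsion* from the classical nuclei,
## attraction to the electronic density, protonic Coulomb with full exact
## exchange K^pp (no proton-proton correlation functional), and the
## proton-side epc potential.  Quantum protons are same-spin fermions, one
## per orbital, so a single proton is exactly self-interaction-free.
##
## The solver alternates electronic and protonic subcycles (inner tolerances
## a fixed fraction of the outer ones) inside an outer loop enforcing the
## stated thresholds.  The epc potential entering the SCF is scaled by b_epc,
## mirroring how double hybrids treat the scaled DFT correlation potential
## self-consistently; the MP2-type terms are strictly post-SCF.

#' Electronic Fock matrix of the coupled system
#'
#' @param state list with electronic density `De` and protonic density `Dp`
#' @param bundle an `IntegralBundle` with protonic blocks
#' @param functional a `FunctionalParams` (or registry name)
#' @param epc_scale scaling of the epc potential entering the Fock matrix
#'   (b_epc by default inside the solver)
#' @param epc parameters of the epc functional
#' @return Fock matrix in the electronic AO basis
#' @export
build_electronic_fock <- function(state, bundle, functional, epc_scale = NULL,
                                  epc = epc_params()) {
  fp <- if (inherits(functional, "FunctionalParams")) functional else
    get_functional(functional)
  if (is.null(epc_scale)) epc_scale <- fp$b_epc
  De <- state$De
  jk <- cpp_jk(bundle$eri_ee, bundle$n_e, De)
  F <- bundle$T - bundle$V + jk$J - 0.5 * fp$a_ex * jk$K
  dens_e <- NULL
  if (length(fp$xc_scf) > 0) {
    dens_e <- grid_density(bundle$phi_e, De)
    F <- F + xc_energy_potential(bundle$phi_e, bundle$grid$weights, dens_e,
                                 fp$xc_scf)$V
  }
  if (bundle$n_p > 0 && !is.null(state$Dp)) {
    cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, De, state$Dp)
    F <- F - cj$V1
    if (epc_scale != 0) {
      if (is.null(dens_e)) dens_e <- grid_density(bundle$phi_e, De)
      dens_p <- grid_density(bundle$phi_p, state$Dp)
      vp <- epc_potentials(dens_e$rho, dens_p$rho, epc)
      w <- bundle$grid$weights
      F <- F + epc_scale *
        crossprod(bundle$phi_e$val, bundle$phi_e$val * (w * vp$v_e))
    }
  }
  0.5 * (F + t(F))
}

#' Protonic Fock matrix of the coupled system
#'
#' Contains no proton-proton correlation functional term: only Coulomb plus
#' full exact exchange among the quantum protons, the repulsion from the
#' classical nuclei, the attraction to the electronic density, and the scaled
#' proton-side epc potential.
#'
#' @inheritParams build_electronic_fock
#' @return Fock matrix in the protonic AO basis
#' @export
build_protonic_fock <- function(state, bundle, epc_scale = 0,
                                epc = epc_params()) {
  Dp <- state$Dp
  jk <- cpp_jk(bundle$eri_pp, bundle$n_p, Dp)
  F <- bundle$Tp + bundle$Vp + jk$J - jk$K
  if (!is.null(state$De)) {
    cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, state$De, Dp)
    F <- F - cj$V2
    if (epc_scale != 0) {
      dens_e <- grid_density(bundle$phi_e, state$De)
      dens_p <- grid_density(bundle$phi_p, Dp)
      vp <- epc_potentials(dens_e$rho, dens_p$rho, epc)
      w <- bundle$grid$weights
      F <- F + epc_scale *
        crossprod(bundle$phi_p$val, bundle$phi_p$val * (w * vp$v_p))
    }
  }
  0.5 * (F + t(F))
}

## total NEO-DFT energy and components at given densities
neo_energy_components <- function(bundle, fp, De, Dp, epc = epc_params()) {
  jk_e <- cpp_jk(bundle$eri_ee, bundle$n_e, De)
  jk_p <- cpp_jk(bundle$eri_pp, bundle$n_p, Dp)
  cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, De, Dp)
  has_grid <- !is.null(bundle$grid)
  w <- if (has_grid) bundle$grid$weights else NULL
  dens_e <- if (has_grid) grid_density(bundle$phi_e, De) else NULL
  dens_p <- if (has_grid) grid_density(bundle$phi_p, Dp) else NULL
  E_e1 <- sum(De * (bundle$T - bundle$V))
  E_Je <- 0.5 * sum(De * jk_e$J)
  E_ex_hf <- -0.25 * sum(De * jk_e$K)
  E_xc <- if (length(fp$xc_scf) > 0) {
    xc_energy_potential(bundle$phi_e, w, dens_e, fp$xc_scf)$E
  } else 0
  E_p1 <- sum(Dp * (bundle$Tp + bundle$Vp))
  E_Jp <- 0.5 * sum(Dp * (jk_p$J - jk_p$K))
  E_ep <- -sum(De * cj$V1)
  E_epc <- if (has_grid) epc_energy(dens_e$rho, dens_p$rho, w, epc) else 0
  E_nn <- nuclear_repulsion(bundle$mol)
  total <- E_e1 + E_Je + fp$a_ex * E_ex_hf + E_xc + E_p1 + E_Jp + E_ep +
    fp$b_epc * E_epc + E_nn
  list(total = total, E_e1 = E_e1, E_Je = E_Je, E_ex_hf = E_ex_hf,
       E_xc = E_xc, E_p1 = E_p1, E_Jp = E_Jp, E_ep = E_ep, E_epc = E_epc,
       E_nn = E_nn, dens_e = dens_e, dens_p = dens_p)
}

#' Coupled electron-proton SCF with post-SCF MP2 terms
#'
#' Runs the multicomponent Kohn-Sham SCF to the stated thresholds and, for
#' double-hybrid functionals, evaluates the spin-resolved electronic MP2 and
#' the electron-proton MP2 terms on the converged orbitals.  Electronic basis
#' functions are placed on the classical nuclei and on every quantum-proton
#' center (hydrogen set).
#'
#' @param mol a `QuantumMolecule` with at least one quantum proton (with
#'   zero quantum protons the calculation reduces to `run_rks`)
#' @param basis a `BasisConfiguration`
#' @param functional registry name or `FunctionalParams`
#' @param settings an `SCFSettings`
#' @param grid_level quadrature grid level
#' @param guess "classical" (electronic guess from a converged
#'   single-component run with the protons as classical hydrogens), "sad", or
#'   "core"
#' @param frozen_core electronic frozen-core policy for MP2
#' @param bundle optional prebuilt `IntegralBundle` (e.g. a hand-set fixture);
#'   bundles without a quadrature grid require `b_epc = 0` functionals
#' @param verbose print macro-iteration log
#' @return list with `energy`, `breakdown`, `state` (an `NEOState`), and the
#'   `functional` used
#' @export
run_neo_scf <- function(mol, basis = basis_configuration(),
                        functional = "neo-b2plyp",
                        settings = scf_settings(), grid_level = 3,
                        guess = "classical", frozen_core = "auto",
                        bundle = NULL, verbose = FALSE) {
  fp <- if (inherits(functional, "FunctionalParams")) functional else
    get_functional(functional)
  np <- nrow(mol$quantum_protons)
  if (np == 0) {
    return(run_rks(mol, basis, fp, settings, grid_level,
                   frozen_core = frozen_core, verbose = verbose))
  }
  if (mol$n_electrons %% 2L != 0L) stop("open-shell systems not supported")
  if (is.null(bundle)) bundle <- build_neo_bundle(mol, basis, grid_level)
  if (is.null(bundle$grid) && (fp$b_epc != 0 || length(fp$xc_scf) > 0)) {
    stop("bundle has no quadrature grid: only b_epc = 0 HF-type functionals ",
         "can be run on it")
  }
  nocc_e <- mol$n_electrons %/% 2L
  w <- if (!is.null(bundle$grid)) bundle$grid$weights else NULL
  ## --- initial electronic density
  De <- NULL
  if (identical(guess, "classical") && length(mol$symbols) > 0) {
    cl <- tryCatch({
      clmol <- quantum_molecule(c(mol$symbols, rep("H", np)),
                                rbind(mol$coords, mol$quantum_protons),
                                charge = mol$charge)
      clb <- build_integrals(clmol, basis, grid_level = grid_level,
                             with_grid = length(fp$xc_scf) > 0)
      rks_from_bundle(clb, fp, scf_settings(energy_tol = 1e-6,
                                            density_tol = 1e-4,
                                            grad_tol = 1e-3))
    }, error = function(e) NULL)
    if (!is.null(cl)) De <- cl$scf$D
  }
  if (is.null(De) && identical(guess, "sad")) {
    De <- tryCatch({
      bdef <- resolve_electronic_basis(basis, unique(c(mol$symbols, "H")))
      sad_guess(quantum_molecule(c(mol$symbols, rep("H", np)),
                                 rbind(mol$coords, mol$quantum_protons),
                                 charge = mol$charge),
                bdef, bundle$shells_e, bundle$S, mol$n_electrons)
    }, error = function(e) NULL)
  }
  if (is.null(De)) {
    ## electronic core guess
    Xe <- orthogonalizer(bundle$S)
    eve <- eigen(t(Xe) %*% (bundle$T - bundle$V) %*% Xe, symmetric = TRUE)
    orde <- order(eve$values)
    Ce0 <- Xe %*% eve$vectors[, orde[seq_len(nocc_e)], drop = FALSE]
    De <- 2 * tcrossprod(Ce0)
  }
  ## --- initial protonic density: core Hamiltonian plus the static
  ## attraction to the guess electronic density (the bare protonic core is
  ## purely repulsive and would be unbound)
  cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, De,
                    matrix(0, bundle$n_p, bundle$n_p))
  hp_eff <- bundle$Tp + bundle$Vp - cj$V2
  Xp <- orthogonalizer(bundle$Sp)
  evp <- eigen(t(Xp) %*% hp_eff %*% Xp, symmetric = TRUE)
  ordp <- order(evp$values)
  Cp <- Xp %*% evp$vectors[, ordp[seq_len(np)], drop = FALSE]
  Dp <- tcrossprod(Cp)
  ## --- macro-iterations with species subcycles
  inner <- scf_settings(
    energy_tol = settings$energy_tol / settings$subcycle_scale * 1e-2,
    density_tol = settings$density_tol * 0.5,
    grad_tol = settings$grad_tol * 0.5,
    diis_len = settings$diis_len, diis_start = settings$diis_start,
    max_iter = 40L, damping = 0)
  Eold <- Inf
  log <- data.frame()
  converged <- FALSE
  scf_e <- scf_p <- NULL
  for (mac in seq_len(settings$max_iter)) {
    ## electronic subcycle at fixed protonic density
    cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, De, Dp)
    dens_p <- if (fp$b_epc != 0) grid_density(bundle$phi_p, Dp) else NULL
    coup_e <- function(D) {
      if (fp$b_epc == 0) return(list(E = 0, V = 0))
      dens_e <- grid_density(bundle$phi_e, D)
      vp <- epc_potentials(dens_e$rho, dens_p$rho)
      E <- fp$b_epc * epc_energy(dens_e$rho, dens_p$rho, w)
      V <- fp$b_epc * crossprod(bundle$phi_e$val,
                                bundle$phi_e$val * (w * vp$v_e))
      list(E = E, V = 0.5 * (V + t(V)))
    }
    scf_e <- species_scf(
      list(S = bundle$S, h = bundle$T - bundle$V - cj$V1,
           eri = bundle$eri_ee, phi = bundle$phi_e, w = w),
      occ = rep(2, nocc_e), exchange = "closed_shell", a_ex = fp$a_ex,
      xc_weights = fp$xc_scf, coupling = coup_e,
      settings = inner, D0 = De)
    De <- scf_e$D
    ## protonic subcycle at fixed electronic density
    cj <- cpp_cross_j(bundle$eri_ep, bundle$n_e, bundle$n_p, De, Dp)
    dens_e <- if (fp$b_epc != 0) grid_density(bundle$phi_e, De) else NULL
    coup_p <- function(D) {
      if (fp$b_epc == 0) return(list(E = 0, V = 0))
      dp <- grid_density(bundle$phi_p, D)
      vp <- epc_potentials(dens_e$rho, dp$rho)
      E <- fp$b_epc * epc_energy(dens_e$rho, dp$rho, w)
      V <- fp$b_epc * crossprod(bundle$phi_p$val,
                                bundle$phi_p$val * (w * vp$v_p))
      list(E = E, V = 0.5 * (V + t(V)))
    }
    scf_p <- species_scf(
      list(S = bundle$Sp, h = bundle$Tp + bundle$Vp - cj$V2,
           eri = bundle$eri_pp),
      occ = rep(1, np), exchange = "same_spin",
      coupling = coup_p, settings = inner, D0 = Dp)
    Dp <- scf_p$D
    comp <- neo_energy_components(bundle, fp, De, Dp)
    dE <- comp$total - Eold
    log <- rbind(log, data.frame(macro = mac, E = comp$total, dE = dE,
                                 grad_e = utils::tail(scf_e$log$grad, 1),
                                 grad_p = utils::tail(scf_p$log$grad, 1)))
    if (verbose) {
      message(sprintf("macro %2d  E = %.10f  dE = %.3e", mac, comp$total, dE))
    }
    if (abs(dE) < settings$energy_tol &&
        utils::tail(scf_e$log$grad, 1) < settings$grad_tol &&
        utils::tail(scf_p$log$grad, 1) < settings$grad_tol) {
      converged <- TRUE
      break
    }
    Eold <- comp$total
  }
  if (!converged) {
    stop("NEO-SCF failed to converge within ", settings$max_iter,
         " macro-iterations (last dE = ",
         format(utils::tail(log$dE, 1), digits = 3), ")")
  }
  comp <- neo_energy_components(bundle, fp, De, Dp)
  state <- structure(list(
    Ce = scf_e$C, eps_e = scf_e$eps, occ_e = rep(2, nocc_e), De = De,
    Cp = scf_p$C, eps_p = scf_p$eps, occ_p = rep(1, np), Dp = Dp,
    log = log, converged = converged), class = "NEOState")
  ## --- breakdown and post-SCF MP2 terms
  bd <- new_energy_breakdown(
    E_ext_ref = comp$E_e1 + comp$E_Je + comp$E_p1 + comp$E_Jp + comp$E_ep +
      comp$E_nn,
    E_ex_hf = comp$E_ex_hf,
    E_xc_scf = comp$E_xc,
    E_epc_dft = comp$E_epc,
    E_disp = 0
  )
  if (fp$family != "hybrid") {
    bd$E_ex_dft <- xc_energy_only(w, comp$dens_e, fp$ex_dft)
    bd$E_ec_dft <- xc_energy_only(w, comp$dens_e, fp$ec_dft)
    nfr <- frozen_core_count(mol, frozen_core)
    mp2 <- electronic_mp2(scf_e$C, scf_e$eps, nocc_e, bundle$eri_ee,
                          frozen = nfr)
    bd$E_ec_mp2_os <- mp2$E_os
    bd$E_ec_mp2_ss <- mp2$E_ss
  }
  if (fp$c_epc != 0 || fp$family != "hybrid") {
    bd$E_epc_mp2 <- ep_mp2_energy(scf_e$C, scf_e$eps, nocc_e,
                                  scf_p$C, scf_p$eps, np, bundle$eri_ep,
                                  frozen_e = frozen_core_count(mol, frozen_core))
  } else bd$E_epc_mp2 <- 0
  bd$meta <- list(functional = fp$name, n_e = bundle$n_e, n_p = bundle$n_p,
                  n_macro = nrow(log), converged = converged)
  list(energy = assemble_energy(bd, fp), breakdown = bd, state = state,
       functional = fp, bundle = bundle)
}

#' @export
print.NEOState <- function(x, ...) {
  cat("NEOState:", length(x$occ_e), "electron pairs,", length(x$occ_p),
      "quantum protons; converged:", x$converged, "in", nrow(x$log),
      "macro-iterations\n")
  invisible(x)
}

## bundle for a NEO system: electronic shells on classical nuclei + proton
## centers (hydrogen electronic set)
build_neo_bundle <- function(mol, basis, grid_level) {
  np <- nrow(mol$quantum_protons)
  tm <- sph_tmats()
  sym_e <- c(mol$symbols, rep("H", np))
  cen_e <- rbind(mol$coords, mol$quantum_protons)
  bdef <- resolve_electronic_basis(basis, unique(sym_e))
  shells_e <- build_shell_list(sym_e, cen_e, bdef)
  Te <- sph_tmat_full(shells_e)
  one <- cpp_one_ints(shells_e)
  chg <- classical_charges(mol)
  S <- Te %*% one$S %*% t(Te)
  K <- Te %*% one$T %*% t(Te)
  V <- Te %*% cpp_nuclear(shells_e, chg$cen, chg$q) %*% t(Te)
  shells_p <- protonic_shell_list(basis$protonic, mol$quantum_protons)
  Tp <- sph_tmat_full(shells_p)
  onep <- cpp_one_ints(shells_p)
  bundle <- list(mol = mol, basis = basis, shells_e = shells_e,
                 shells_p = shells_p, n_e = shells_e$nbf, n_p = shells_p$nbf,
                 S = S, T = K, V = V,
                 Sp = Tp %*% onep$S %*% t(Tp),
                 Tp = (Tp %*% onep$T %*% t(Tp)) / neodh_constants$proton_mass_au,
                 Vp = Tp %*% cpp_nuclear(shells_p, chg$cen, chg$q) %*% t(Tp))
  bundle$eri_ee <- cpp_eri(shells_e, shells_e, tm, TRUE, 1e-12)
  bundle$eri_pp <- cpp_eri(shells_p, shells_p, tm, TRUE, 1e-14)
  bundle$eri_ep <- cpp_eri(shells_e, shells_p, tm, FALSE, 1e-14)
  g <- molecular_grid(mol, grid_level)
  bundle$grid <- g
  bundle$phi_e <- cpp_ao_grid(shells_e, g$points, tm)
  bundle$phi_p <- cpp_ao_grid(shells_p, g$points, tm)
  class(bundle) <- "IntegralBundle"
  bundle
}
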
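## Integral provider: assembles every one- and two-particle integral block a
## multicomponent SCF needs, for both particle types, plus the quadrature
## grid with basis amplitudes.  Two-electron integrals are available as
## conventional full tensors and (optionally) as fitted three-index tensors
## sharing a Coulomb metric.

#' Build the integral bundle for a system
#'
#' One- and two-particle integrals over the electronic and protonic bases.
#' The protonic kinetic matrix carries the 1/m_p mass factor; the protonic
#' external potential is repulsive towards the (positive) classical nuclei.
#' Quantum protons contribute no point charge to the electronic external
#' potential: electrons see them only through the mixed Coulomb block.
#'
#' @param mol a `QuantumMolecule`
#' @param basis a `BasisConfiguration`
#' @param grid_level quadrature grid level (1-5)
#' @param two_electron "conventional" (full 4-index tensors), "df" (also build
#'   fitted 3-index tensors), or "none"
#' @param with_grid logical: build the quadrature grid and AO amplitudes
#' @return an `IntegralBundle`
#' @export
build_integrals <- function(mol, basis = basis_configuration(),
                            grid_level = 3, two_electron = "conventional",
                            with_grid = TRUE) {
  tm <- sph_tmats()
  bdef <- resolve_electronic_basis(basis, unique(mol$symbols))
  shells_e <- build_shell_list(mol$symbols, mol$coords, bdef)
  Te <- sph_tmat_full(shells_e)
  one <- cpp_one_ints(shells_e)
  chg <- classical_charges(mol)
  S <- Te %*% one$S %*% t(Te)
  K <- Te %*% one$T %*% t(Te)
  V <- if (length(chg$q) > 0) {
    Te %*% cpp_nuclear(shells_e, chg$cen, chg$q) %*% t(Te)
  } else 0 * S
  np <- nrow(mol$quantum_protons)
  bundle <- list(mol = mol, basis = basis, shells_e = shells_e,
                 n_e = shells_e$nbf, S = S, T = K, V = V,
                 n_p = 0L, shells_p = NULL)
  if (np > 0) {
    shells_p <- protonic_shell_list(basis$protonic, mol$quantum_protons)
    Tp <- sph_tmat_full(shells_p)
    onep <- cpp_one_ints(shells_p)
    Sp <- Tp %*% onep$S %*% t(Tp)
    Kp <- (Tp %*% onep$T %*% t(Tp)) / neodh_constants$proton_mass_au
    Vp <- if (length(chg$q) > 0) {
      Tp %*% cpp_nuclear(shells_p, chg$cen, chg$q) %*% t(Tp)
    } else 0 * Sp
    bundle$shells_p <- shells_p
    bundle$n_p <- shells_p$nbf
    bundle$Sp <- Sp
    bundle$Tp <- Kp
    bundle$Vp <- Vp
  }
  if (two_electron %in% c("conventional", "df")) {
    bundle$eri_ee <- cpp_eri(shells_e, shells_e, tm, TRUE, 1e-12)
    if (np > 0) {
      bundle$eri_pp <- cpp_eri(bundle$shells_p, bundle$shells_p, tm, TRUE, 1e-14)
      bundle$eri_ep <- cpp_eri(shells_e, bundle$shells_p, tm, FALSE, 1e-14)
    }
  }
  if (two_electron == "df") {
    bundle <- add_df_tensors(bundle)
  }
  if (with_grid) {
    g <- molecular_grid(mol, grid_level)
    bundle$grid <- g
    bundle$phi_e <- cpp_ao_grid(shells_e, g$points, tm)
    if (np > 0) bundle$phi_p <- cpp_ao_grid(bundle$shells_p, g$points, tm)
  }
  class(bundle) <- "IntegralBundle"
  bundle
}

#' @export
print.IntegralBundle <- function(x, ...) {
  cat("IntegralBundle:", x$n_e, "electronic AOs,", x$n_p, "protonic AOs",
      if (!is.null(x$grid)) sprintf(", %d grid points", nrow(x$grid$points)),
      "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Density fitting

## even-tempered automatic auxiliary set generated from the orbital exponents
## of a per-element basis definition (Coulomb-metric fitting)
auto_fitting_def <- function(bdef) {
  out <- list()
  for (el in names(bdef)) {
    lmax <- max(vapply(bdef[[el]], function(s) s$l, 0L))
    aux <- list()
    for (laux in 0:min(2L * lmax, 4L)) {
      contributing <- Filter(function(s) TRUE, bdef[[el]])
      ex <- unlist(lapply(contributing, function(s) s$exps))
      lo <- 2 * min(ex) * 0.4
      hi <- 2 * max(ex) * 2.0
      n <- max(4L, ceiling(log(hi / lo) / log(1.8)) + 1L)
      r <- (hi / lo)^(1 / (n - 1))
      for (e in lo * r^(0:(n - 1))) {
        aux[[length(aux) + 1L]] <- list(l = laux, exps = e, coefs = 1)
      }
    }
    out[[el]] <- aux
  }
  out
}

add_df_tensors <- function(bundle) {
  tm <- sph_tmats()
  mol <- bundle$mol
  bdef <- resolve_electronic_basis(bundle$basis)
  fit_e <- if (identical(bundle$basis$electronic_fitting, "auto")) {
    auto_fitting_def(bdef[unique(mol$symbols)])
  } else bundle$basis$electronic_fitting
  aux_e <- build_shell_list(mol$symbols, mol$coords, fit_e)
  aux_shells <- aux_e
  if (bundle$n_p > 0) {
    aux_p <- protonic_shell_list(bundle$basis$protonic_fitting,
                                 mol$quantum_protons)
    ## union of the electronic and protonic fitting sets: one shared metric
    aux_shells <- list(
      l = c(aux_e$l, aux_p$l),
      centers = cbind(aux_e$centers, aux_p$centers),
      exps = c(aux_e$exps, aux_p$exps),
      coefs = c(aux_e$coefs, aux_p$coefs),
      atom_of = c(aux_e$atom_of, aux_p$atom_of + nrow(mol$coords)),
      nbf = aux_e$nbf + aux_p$nbf)
    class(aux_shells) <- "ShellList"
  }
  M <- cpp_eri_2c(aux_shells, tm)
  B_e <- cpp_eri_3c(bundle$shells_e, aux_shells, tm)
  bundle$df <- list(aux = aux_shells, metric = M,
                    metric_chol = tryCatch(chol(M), error = function(e) {
                      chol(M + diag(1e-10, nrow(M)))
                    }),
                    B_e = B_e)
  if (bundle$n_p > 0) {
    bundle$df$B_p <- cpp_eri_3c(bundle$shells_p, aux_shells, tm)
  }
  bundle
}

## fitted Coulomb: J1 felt by species 1 from density D2 of species 2
## J1 = (mu nu|P) M^-1 (Q|ls) D2_ls
df_coulomb <- function(df, B1, B2, D2) {
  n2 <- nrow(D2)
  naux <- nrow(df$metric)
  dim(B2) <- c(n2 * n2, naux)
  rhs <- as.numeric(crossprod(B2, as.numeric(D2)))
  cf <- backsolve(df$metric_chol,
                  backsolve(df$metric_chol, rhs, transpose = TRUE))
  n1sq <- length(B1) / naux
  dim(B1) <- c(n1sq, naux)
  J <- B1 %*% cf
  n1 <- as.integer(sqrt(n1sq))
  matrix(J, n1, n1)
}

## ---------------------------------------------------------------------------

#' Diagnostics for an integral bundle
#'
#' Reports symmetry defects of the one-particle matrices, overlap eigenvalue
#' ranges (metric condition), and the grid integral of each normalised basis
#' function square against 1.
#'
#' @param bundle an `IntegralBundle`
#' @return a list of diagnostics
#' @export
validate_bundle <- function(bundle) {
  sym_defect <- function(M) if (is.null(M)) 0 else max(abs(M - t(M)))
  out <- list(
    sym_defect_S = sym_defect(bundle$S),
    sym_defect_T = sym_defect(bundle$T),
    sym_defect_V = sym_defect(bundle$V),
    overlap_eigen_range = range(eigen(bundle$S, symmetric = TRUE,
                                      only.values = TRUE)$values)
  )
  if (bundle$n_p > 0) {
    out$sym_defect_Sp <- sym_defect(bundle$Sp)
    out$overlap_eigen_range_p <- range(eigen(bundle$Sp, symmetric = TRUE,
                                             only.values = TRUE)$values)
  }
  if (!is.null(bundle$grid)) {
    w <- bundle$grid$weights
    out$grid_selfoverlap <- colSums(w * bundle$phi_e$val^2)
    out$grid_selfoverlap_max_err <- max(abs(out$grid_selfoverlap - 1))
    out$grid_weights_positive <- all(w > 0)
  }
  out
}
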
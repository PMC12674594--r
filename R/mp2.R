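## Second-order perturbative correlation on converged (multicomponent)
## Kohn-Sham orbitals: spin-resolved closed-shell electronic MP2 and the
## electron-proton MP2 term from simultaneous single excitations of both
## species coupled by the electron-proton Coulomb operator.

## number of frozen chemical-core spatial orbitals for a molecule
frozen_core_count <- function(mol, policy = "auto") {
  if (identical(policy, "none")) return(0L)
  core_of <- function(Z) {
    if (Z <= 2) 0L else if (Z <= 10) 1L else if (Z <= 18) 5L else
      stop("no frozen-core convention tabulated for Z = ", Z)
  }
  sum(vapply(mol$Z, core_of, 0L))
}

## MO integral block (ia|jb) by successive quarter transforms
mo_eri_ovov <- function(eri, n, Cocc, Cvir) {
  no <- ncol(Cocc); nv <- ncol(Cvir)
  dim(eri) <- c(n, n^3)
  A <- crossprod(Cocc, eri)                 # (no, q r s)
  dim(A) <- c(no, n, n, n)
  A <- apply_mode(A, Cvir, 2L)              # (no, nv, r, s)
  A <- apply_mode(A, Cocc, 3L)              # (no, nv, no, s)
  A <- apply_mode(A, Cvir, 4L)              # (no, nv, no, nv)
  A
}

## contract mode k of a 4-index array with transformation matrix (rows AO)
apply_mode <- function(A, C, k) {
  d <- dim(A)
  perm <- c(k, setdiff(1:4, k))
  Ap <- aperm(A, perm)
  dim(Ap) <- c(d[k], prod(d[-k]))
  Bp <- crossprod(C, Ap)
  dim(Bp) <- c(ncol(C), d[perm[2]], d[perm[3]], d[perm[4]])
  aperm(Bp, order(perm))
}

## ---------------------------------------------------------------------------
## density-fitted MO tensors: whitened B~_ia^P with (ia|jb) = B~_ia . B~_jb

## B3: 3-index AO tensor (n, n, naux); returns matrix (no*nv, naux)
df_whitened_ovP <- function(B3, metric_chol, Cocc, Cvir) {
  n <- dim(B3)[1]; naux <- dim(B3)[3]
  no <- ncol(Cocc); nv <- ncol(Cvir)
  out <- matrix(0, no * nv, naux)
  for (P in seq_len(naux)) {
    out[, P] <- as.numeric(crossprod(Cocc, B3[, , P] %*% Cvir))
  }
  ## whiten with the inverse Cholesky factor of the Coulomb metric
  t(backsolve(metric_chol, t(out), transpose = TRUE))
}

#' Density-fitted spin-resolved electronic MP2
#'
#' Assembles the (ia|jb) block from fitted 3-index tensors sharing a Coulomb
#' metric and evaluates the same spin-resolved second-order expressions as
#' [electronic_mp2()] (which serves as the unfitted reference).
#'
#' @inheritParams electronic_mp2
#' @param B3 3-index AO tensor `(mu nu | P)` with dims (n, n, naux)
#' @param metric_chol Cholesky factor of the auxiliary Coulomb metric
#' @return list with `E_os`, `E_ss`, `E_total`
#' @export
electronic_mp2_df <- function(C, eps, nocc, B3, metric_chol, frozen = 0L) {
  act <- (frozen + 1L):nocc
  vir <- seq_len(ncol(C))[-seq_len(nocc)]
  if (length(vir) == 0) return(list(E_os = 0, E_ss = 0, E_total = 0))
  Bw <- df_whitened_ovP(B3, metric_chol, C[, act, drop = FALSE],
                        C[, vir, drop = FALSE])
  no <- length(act); nv <- length(vir)
  G <- array(tcrossprod(Bw), c(no, nv, no, nv))
  mp2_from_ovov(G, eps[act], eps[vir])
}

#' Density-fitted electron-proton MP2 energy
#'
#' The mixed block `(ia|i'a')` is assembled from the electronic and protonic
#' 3-index tensors over one shared auxiliary metric.
#'
#' @inheritParams ep_mp2_energy
#' @param Be3,Bp3 3-index AO tensors of each species over the shared
#'   auxiliary set
#' @param metric_chol Cholesky factor of the shared Coulomb metric
#' @return energy in hartree
#' @export
ep_mp2_energy_df <- function(Ce, eps_e, nocc_e, Cp, eps_p, nocc_p,
                             Be3, Bp3, metric_chol, frozen_e = 0L) {
  act <- (frozen_e + 1L):nocc_e
  vir_e <- seq_len(ncol(Ce))[-seq_len(nocc_e)]
  occ_p <- seq_len(nocc_p)
  vir_p <- seq_len(ncol(Cp))[-occ_p]
  if (length(vir_e) == 0 || length(vir_p) == 0) return(0)
  Bwe <- df_whitened_ovP(Be3, metric_chol, Ce[, act, drop = FALSE],
                         Ce[, vir_e, drop = FALSE])
  Bwp <- df_whitened_ovP(Bp3, metric_chol, Cp[, occ_p, drop = FALSE],
                         Cp[, vir_p, drop = FALSE])
  A <- array(tcrossprod(Bwe, Bwp),
             c(length(act), length(vir_e), length(occ_p), length(vir_p)))
  ep_energy_from_tensor(A, eps_e[act], eps_e[vir_e], eps_p[occ_p],
                        eps_p[vir_p])
}

## shared second-order summations -------------------------------------------

mp2_from_ovov <- function(G, eo, ev) {
  no <- length(eo); nv <- length(ev)
  Dt <- outer(eo, -ev, `+`)
  den <- array(0, dim = c(no, nv, no, nv))
  for (j in seq_len(no)) for (b in seq_len(nv)) {
    den[, , j, b] <- Dt + (eo[j] - ev[b])
  }
  if (any(abs(den) < 1e-10)) {
    stop("degenerate occupied-virtual denominator in MP2")
  }
  Gx <- aperm(G, c(1, 4, 3, 2))
  E_os <- sum(G * G / den)
  E_ss <- sum(G * (G - Gx) / den)
  list(E_os = E_os, E_ss = E_ss, E_total = E_os + E_ss)
}

ep_energy_from_tensor <- function(A, eo, ev, eop, evp) {
  den_e <- outer(eo, -ev, `+`)
  den_p <- outer(eop, -evp, `+`)
  E <- 0
  for (ip in seq_along(eop)) for (ap in seq_along(evp)) {
    dd <- den_e + den_p[ip, ap]
    if (any(abs(dd) < 1e-10)) {
      stop("degenerate denominator in electron-proton MP2 (protonic pair ",
           ip, "->", ap, ")")
    }
    E <- E + sum(A[, , ip, ap]^2 / dd)
  }
  2 * E
}

#' Spin-resolved closed-shell electronic MP2
#'
#' Standard MP2 on the converged orbitals, split into opposite-spin and
#' same-spin components:
#' `E_os = sum (ia|jb)^2 / D`, `E_ss = sum (ia|jb)[(ia|jb) - (ib|ja)] / D`
#' with `D = e_i + e_j - e_a - e_b`.
#'
#' @param C orbital coefficient matrix (AO x MO)
#' @param eps orbital energies
#' @param nocc number of doubly occupied spatial orbitals
#' @param eri full AO integral tensor (chemist notation)
#' @param frozen number of frozen core spatial orbitals
#' @return list with `E_os`, `E_ss`, `E_total`
#' @export
electronic_mp2 <- function(C, eps, nocc, eri, frozen = 0L) {
  n <- nrow(C)
  act <- (frozen + 1L):nocc
  vir <- seq_len(ncol(C))[-seq_len(nocc)]
  if (length(vir) == 0) return(list(E_os = 0, E_ss = 0, E_total = 0))
  Co <- C[, act, drop = FALSE]; Cv <- C[, vir, drop = FALSE]
  G <- mo_eri_ovov(eri, n, Co, Cv)          # (i, a, j, b)
  mp2_from_ovov(G, eps[act], eps[vir])
}

#' Electron-proton MP2 correlation energy
#'
#' Second-order energy from simultaneous single excitations of the electrons
#' (i -> a) and of the quantum protons (i' -> a'), coupled by the attractive
#' electron-proton Coulomb interaction:
#' `E = 2 sum |(ia|i'a')|^2 / (e_i - e_a + e_i' - e_a')`
#' (factor 2 from the electron spin sum; closed-shell electrons).
#' Pure-electronic and pure-protonic singles are omitted, as in standard
#' double-hybrid practice.
#'
#' @param Ce,eps_e,nocc_e electronic orbitals, energies, occupied count
#' @param Cp,eps_p,nocc_p protonic orbitals, energies, occupied count
#' @param eri_ep mixed AO tensor (mu nu | mu' nu'), positive-kernel Coulomb
#' @param frozen_e frozen electronic core orbitals
#' @return energy in hartree (non-positive for Aufbau-converged references)
#' @export
ep_mp2_energy <- function(Ce, eps_e, nocc_e, Cp, eps_p, nocc_p, eri_ep,
                          frozen_e = 0L) {
  ne <- nrow(Ce); npb <- nrow(Cp)
  act <- (frozen_e + 1L):nocc_e
  vir_e <- seq_len(ncol(Ce))[-seq_len(nocc_e)]
  occ_p <- seq_len(nocc_p)
  vir_p <- seq_len(ncol(Cp))[-occ_p]
  if (length(vir_e) == 0 || length(vir_p) == 0) return(0)
  dim(eri_ep) <- c(ne, ne, npb, npb)
  A <- apply_mode(eri_ep, Ce[, act, drop = FALSE], 1L)
  A <- apply_mode(A, Ce[, vir_e, drop = FALSE], 2L)
  A <- apply_mode(A, Cp[, occ_p, drop = FALSE], 3L)
  A <- apply_mode(A, Cp[, vir_p, drop = FALSE], 4L)
  ## A[i, a, i', a'] holds (ia|i'a') with the positive kernel; the coupling is
  ## attractive (-1/r), but only |.|^2 enters
  ep_energy_from_tensor(A, eps_e[act], eps_e[vir_e], eps_p[occ_p],
                        eps_p[vir_p])
}
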
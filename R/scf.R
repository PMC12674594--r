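## Self-consistent field machinery shared by the electronic and protonic
## species: canonical orthogonalization with linear-dependence pruning, Pulay
## DIIS, exchange-correlation quadrature, and a species-generic SCF driver.
## Electrons are spin-restricted closed shell (F = h + J - a/2 K + Vxc);
## quantum protons are same-spin fermions in one determinant (F = h + J - K),
## which makes a single proton exactly self-interaction-free (J = K).

#' SCF convergence settings
#'
#' Defaults follow the working protocol of the package: energy threshold
#' 1e-8 Eh, density and orbital-gradient thresholds 1e-5 a.u., DIIS over the
#' last 10 Fock matrices starting after the first iteration.
#'
#' @param energy_tol,density_tol,grad_tol convergence thresholds
#' @param diis_len DIIS history length
#' @param diis_start iteration at which DIIS extrapolation begins
#' @param max_iter maximum macro-iterations
#' @param damping initial density damping factor (0 disables)
#' @param subcycle_scale inner (species subcycle) tolerances as a multiple of
#'   the outer thresholds in coupled runs
#' @return an `SCFSettings` list
#' @export
scf_settings <- function(energy_tol = 1e-8, density_tol = 1e-5,
                         grad_tol = 1e-5, diis_len = 10L, diis_start = 2L,
                         max_iter = 120L, damping = 0.35,
                         subcycle_scale = 1e-2) {
  stopifnot(energy_tol > 0, density_tol > 0, grad_tol > 0, diis_len >= 1)
  structure(list(energy_tol = energy_tol, density_tol = density_tol,
                 grad_tol = grad_tol, diis_len = as.integer(diis_len),
                 diis_start = as.integer(diis_start),
                 max_iter = as.integer(max_iter), damping = damping,
                 subcycle_scale = subcycle_scale),
            class = "SCFSettings")
}

## canonical orthogonalizer with relative eigenvalue pruning
orthogonalizer <- function(S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values)
  n_pruned <- sum(!keep)
  X <- ev$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ev$values[keep]), sum(keep))
  attr(X, "n_pruned") <- n_pruned
  X
}

#' Pulay DIIS extrapolation
#'
#' Least-squares combination of the stored Fock matrices that minimises the
#' norm of the combined error vector under the constraint that coefficients
#' sum to one.  Falls back to the most recent Fock matrix when the DIIS
#' system is numerically singular.
#'
#' @param history list of `list(F =, err =)` pairs, oldest first
#' @param max_len maximum history length retained
#' @return list with the extrapolated `F`, the truncated `history`, and the
#'   `coef` used
#' @export
diis_update <- function(history, max_len = 10L) {
  if (length(history) == 0) stop("DIIS history is empty")
  if (length(history) > max_len) {
    history <- history[(length(history) - max_len + 1L):length(history)]
  }
  m <- length(history)
  if (m == 1L) {
    return(list(F = history[[1]]$F, history = history, coef = 1))
  }
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[i, j] <- sum(history[[i]]$err * history[[j]]$err)
  }
  B[m + 1, seq_len(m)] <- 1
  B[seq_len(m), m + 1] <- 1
  rhs <- c(rep(0, m), 1)
  coef <- tryCatch({
    sol <- solve(B, rhs)
    sol[seq_len(m)]
  }, error = function(e) NULL)
  if (is.null(coef) || any(!is.finite(coef))) {
    return(list(F = history[[m]]$F, history = history, coef = NULL))
  }
  Fx <- 0
  for (i in seq_len(m)) Fx <- Fx + coef[i] * history[[i]]$F
  list(F = Fx, history = history, coef = coef)
}

## ---------------------------------------------------------------------------
## Exchange-correlation quadrature

## density and |grad rho|^2 on the grid from AO amplitudes and density matrix
grid_density <- function(phi, D) {
  PD <- phi$val %*% D
  rho <- rowSums(PD * phi$val)
  gx <- 2 * rowSums(PD * phi$dx)
  gy <- 2 * rowSums(PD * phi$dy)
  gz <- 2 * rowSums(PD * phi$dz)
  list(rho = pmax(rho, 0), gx = gx, gy = gy, gz = gz,
       gam = gx^2 + gy^2 + gz^2)
}

## energy and potential matrix of a weighted set of xc pieces
xc_energy_potential <- function(phi, w, dens, xc_weights) {
  if (length(xc_weights) == 0) {
    n <- ncol(phi$val)
    return(list(E = 0, V = matrix(0, n, n)))
  }
  e <- vr <- vg <- 0
  for (nm in names(xc_weights)) {
    ev <- xc_eval(nm, dens$rho, dens$gam)
    wgt <- xc_weights[[nm]]
    e <- e + wgt * ev$e
    vr <- vr + wgt * ev$vrho
    vg <- vg + wgt * ev$vgamma
  }
  E <- sum(w * e)
  V <- crossprod(phi$val, phi$val * (w * vr))
  if (any(vg != 0)) {
    gv <- 2 * w * vg
    Bm <- crossprod(phi$val, phi$dx * (gv * dens$gx) +
                      phi$dy * (gv * dens$gy) + phi$dz * (gv * dens$gz))
    V <- V + Bm + t(Bm)
  }
  list(E = E, V = 0.5 * (V + t(V)))
}

## unweighted xc piece-set energy at a fixed density (for EnergyBreakdown)
xc_energy_only <- function(w, dens, pieces) {
  if (length(pieces) == 0) return(0)
  e <- 0
  for (nm in pieces) e <- e + xc_eval(nm, dens$rho, dens$gam)$e
  sum(w * e)
}

## ---------------------------------------------------------------------------
## Species-generic SCF driver
##
## ints: list(S, h, eri, phi (optional), w (grid weights))
## occ: occupation vector applied to the lowest orbitals (e.g. rep(2, nocc))
## exchange: "closed_shell" (F += J - a/2 K) or "same_spin" (F += J - K)
## coupling: function(D) -> list(E =, V =) for extra density-dependent terms
##   (inter-species Coulomb, epc); contributes V to the Fock matrix and E to
##   the reported coupling energy.
species_scf <- function(ints, occ, exchange = "closed_shell", a_ex = 1,
                        xc_weights = list(), coupling = NULL,
                        settings = scf_settings(), D0 = NULL,
                        verbose = FALSE) {
  S <- ints$S; h <- ints$h
  n <- nrow(S)
  X <- orthogonalizer(S)
  nocc <- length(occ)
  fock_pieces <- function(D) {
    jk <- cpp_jk(ints$eri, n, D)
    kf <- if (exchange == "closed_shell") 0.5 * a_ex else 1.0
    ke <- if (exchange == "closed_shell") 0.25 * a_ex else 0.5
    dens <- NULL
    xc <- list(E = 0, V = 0)
    if (length(xc_weights) > 0) {
      dens <- grid_density(ints$phi, D)
      xc <- xc_energy_potential(ints$phi, ints$w, dens, xc_weights)
    }
    cp <- if (is.null(coupling)) list(E = 0, V = 0) else coupling(D)
    F <- h + jk$J - kf * jk$K + xc$V + cp$V
    E1 <- sum(D * h)
    EJ <- 0.5 * sum(D * jk$J)
    EK <- -ke * sum(D * jk$K)
    ## HF-exchange energy with the full (unweighted) factor for reporting
    EKfull <- -(if (exchange == "closed_shell") 0.25 else 0.5) * sum(D * jk$K)
    list(F = F, E = E1 + EJ + EK + xc$E + cp$E, E1 = E1, EJ = EJ, EK = EK,
         EKfull = EKfull, Exc = xc$E, Ecoup = cp$E, dens = dens, K = jk$K)
  }
  ## initial density
  asc <- function(ev) {   # eigen() sorts decreasing; aufbau needs ascending
    list(values = rev(ev$values), vectors = ev$vectors[, rev(seq_along(ev$values)), drop = FALSE])
  }
  if (is.null(D0)) {
    Hx <- t(X) %*% h %*% X
    ev <- asc(eigen(Hx, symmetric = TRUE))
    C <- X %*% ev$vectors[, seq_len(nocc), drop = FALSE]
    D <- C %*% (t(C) * occ)
  } else D <- D0
  history <- list()
  Eold <- Inf; Dold <- D
  log <- data.frame()
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    fp <- fock_pieces(D)
    err <- fp$F %*% D %*% S - S %*% D %*% fp$F
    err <- t(X) %*% err %*% X
    gnorm <- max(abs(err))
    history[[length(history) + 1L]] <- list(F = fp$F, err = err)
    Fuse <- fp$F
    if (it >= settings$diis_start) {
      du <- diis_update(history, settings$diis_len)
      history <- du$history
      Fuse <- du$F
    }
    Fx <- t(X) %*% Fuse %*% X
    ev <- asc(eigen(Fx, symmetric = TRUE))
    C <- X %*% ev$vectors
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    Dnew <- Cocc %*% (t(Cocc) * occ)
    if (settings$damping > 0 && it <= 3 && is.null(D0)) {
      Dnew <- (1 - settings$damping) * Dnew + settings$damping * D
    }
    dE <- fp$E - Eold
    dD <- sqrt(mean((Dnew - D)^2))
    log <- rbind(log, data.frame(iter = it, E = fp$E, dE = dE, dD = dD,
                                 grad = gnorm))
    if (verbose) {
      message(sprintf("  it %3d  E = %.10f  dE = %.2e  dD = %.2e  g = %.2e",
                      it, fp$E, dE, dD, gnorm))
    }
    if (abs(dE) < settings$energy_tol && dD < settings$density_tol &&
        gnorm < settings$grad_tol) {
      converged <- TRUE
      D <- Dnew
      break
    }
    Eold <- fp$E
    D <- Dnew
  }
  fp <- fock_pieces(D)
  eps <- ev$values
  list(C = C, eps = eps, occ = occ, D = D, E = fp$E, E1 = fp$E1, EJ = fp$EJ,
       EK = fp$EK, EKfull = fp$EKfull, Exc = fp$Exc, Ecoup = fp$Ecoup,
       dens = fp$dens, converged = converged, log = log, X = X,
       n_pruned = attr(X, "n_pruned"))
}

## ---------------------------------------------------------------------------
## Atomic SCF with spherically averaged fractional occupations; used for the
## superposition-of-atomic-densities guess and for deriving contraction
## coefficients of the synthetic basis sets.

atomic_occupations <- function(Z) {
  shells <- list(c(l = 0, cap = 2), c(l = 0, cap = 2), c(l = 1, cap = 6),
                 c(l = 0, cap = 2), c(l = 1, cap = 6))
  occ <- numeric(0)
  left <- Z
  for (s in shells) {
    if (left <= 0) break
    take <- min(left, s[["cap"]])
    ndeg <- if (s[["l"]] == 0) 1 else 3
    occ <- c(occ, rep(take / ndeg, ndeg))
    left <- left - take
  }
  occ
}

atomic_scf <- function(symbol, basis_def, settings = scf_settings(
                         energy_tol = 1e-10, density_tol = 1e-7,
                         grad_tol = 1e-7, damping = 0)) {
  Z <- element_Z(symbol)
  sl <- build_shell_list(symbol, matrix(0, 1, 3), basis_def)
  Tf <- sph_tmat_full(sl)
  one <- cpp_one_ints(sl)
  S <- Tf %*% one$S %*% t(Tf)
  K <- Tf %*% one$T %*% t(Tf)
  V <- Tf %*% cpp_nuclear(sl, matrix(0, 3, 1), Z) %*% t(Tf)
  tm <- sph_tmats()
  eri <- cpp_eri(sl, sl, tm, TRUE, 1e-14)
  occ <- atomic_occupations(Z)
  res <- species_scf(list(S = S, h = K - V, eri = eri), occ,
                     exchange = "closed_shell", a_ex = 1,
                     settings = settings)
  ## occupied orbitals sorted by aufbau within the fractional scheme
  res$shells <- sl
  res$S <- S
  res
}

## cache of atomic SCF results keyed by symbol + basis identity
.atomic_cache <- new.env(parent = emptyenv())

atomic_scf_cached <- function(symbol, basis_def) {
  key <- paste0(symbol, "|", digest_basis(basis_def[[symbol]]))
  if (!is.null(.atomic_cache[[key]])) return(.atomic_cache[[key]])
  res <- atomic_scf(symbol, basis_def)
  .atomic_cache[[key]] <- res
  res
}

digest_basis <- function(shlist) {
  paste(vapply(shlist, function(s) {
    paste(s$l, paste(signif(s$exps, 10), collapse = ","),
          paste(signif(s$coefs, 10), collapse = ","), sep = ":")
  }, ""), collapse = ";")
}

## superposition-of-atomic-densities guess in the molecular AO basis,
## scaled so that tr(D S) equals the molecular electron count
sad_guess <- function(mol, basis_def, shells_e, S, nelec) {
  n <- shells_e$nbf
  D <- matrix(0, n, n)
  off <- 0L
  for (i in seq_along(mol$symbols)) {
    at <- atomic_scf_cached(mol$symbols[i], basis_def)
    na <- at$shells$nbf
    idx <- off + seq_len(na)
    D[idx, idx] <- at$D
    off <- off + na
  }
  tr <- sum(D * S)
  if (tr > 0) D * (nelec / tr) else D
}
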
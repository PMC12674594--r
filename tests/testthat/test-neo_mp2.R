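## independent spin-orbital MP2 oracle: antisymmetrized integrals, explicit
## loops over spin orbitals, partitioned by spin case
spin_orbital_mp2 <- function(C, eps, nocc, eri) {
  n <- nrow(C)
  nmo <- ncol(C)
  ## full MO tensor (pq|rs)
  A <- eri
  dim(A) <- c(n, n, n, n)
  A <- neodh:::apply_mode(A, C, 1L)
  A <- neodh:::apply_mode(A, C, 2L)
  A <- neodh:::apply_mode(A, C, 3L)
  A <- neodh:::apply_mode(A, C, 4L)
  ## literal spin-orbital sum: E = 1/4 sum |<ij||ab>|^2 / D, classified by
  ## the spins of the occupied pair
  E_os <- 0; E_ss <- 0
  occ <- seq_len(nocc); vir <- setdiff(seq_len(nmo), occ)
  for (i in occ) for (j in occ) for (a in vir) for (b in vir) {
    den <- eps[i] + eps[j] - eps[a] - eps[b]
    for (si in 1:2) for (sj in 1:2) for (sa in 1:2) for (sb in 1:2) {
      coul <- if (si == sa && sj == sb) A[i, a, j, b] else 0
      exch <- if (si == sb && sj == sa) A[i, b, j, a] else 0
      v <- coul - exch
      if (v == 0) next
      contrib <- 0.25 * v^2 / den
      if (si == sj) E_ss <- E_ss + contrib else E_os <- E_os + contrib
    }
  }
  list(E_os = E_os, E_ss = E_ss)
}

make_toy_electronic <- function(nbf = 4, seed = 11) {
  set.seed(seed)
  cen <- rbind(c(0, 0, 0), c(0, 0, 1.8))
  bd <- list(X = list(list(l = 0L, exps = 1.5, coefs = 1),
                      list(l = 0L, exps = 0.5, coefs = 1)))
  sl <- neodh:::build_shell_list(c("X", "X"), cen, list(X = bd$X))
  tm <- neodh:::sph_tmats()
  eri <- neodh:::cpp_eri(sl, sl, tm, TRUE, 0)
  Tf <- neodh:::sph_tmat_full(sl)
  one <- neodh:::cpp_one_ints(sl)
  S <- Tf %*% one$S %*% t(Tf)
  h <- Tf %*% one$T %*% t(Tf) -
    Tf %*% neodh:::cpp_nuclear(sl, t(cen), c(2, 2)) %*% t(Tf)
  scf <- neodh:::species_scf(list(S = S, h = h, eri = eri), occ = c(2, 2),
                             a_ex = 1)
  list(C = scf$C, eps = scf$eps, eri = eri, n = sl$nbf, scf = scf)
}

test_that("spin-resolved electronic MP2 matches a spin-orbital oracle", {
  toy <- make_toy_electronic()
  mp2 <- electronic_mp2(toy$C, toy$eps, nocc = 2, toy$eri)
  orc <- spin_orbital_mp2(toy$C, toy$eps, 2, toy$eri)
  expect_equal(mp2$E_os, orc$E_os, tolerance = 1e-10)
  expect_equal(mp2$E_ss, orc$E_ss, tolerance = 1e-10)
  expect_equal(mp2$E_total, mp2$E_os + mp2$E_ss, tolerance = 1e-12)
  expect_lt(mp2$E_total, 0)
})

test_that("two electrons in one orbital have zero same-spin correlation", {
  toy <- make_toy_electronic()
  mp2 <- electronic_mp2(toy$C, toy$eps, nocc = 1, toy$eri)
  expect_equal(mp2$E_ss, 0, tolerance = 1e-12)
  expect_lt(mp2$E_os, 0)
  ## zero two-electron integrals give exactly (0, 0)
  z <- electronic_mp2(toy$C, toy$eps, 1, array(0, rep(toy$n, 4)))
  expect_equal(c(z$E_os, z$E_ss), c(0, 0))
})

test_that("electron-proton MP2 reproduces closed forms and brute force", {
  ## single electronic + single protonic pair with coupling t and gap d
  Ce <- diag(2); Cp <- diag(2)
  eps_e <- c(-1, 0.5); eps_p <- c(0.2, 1.0)
  t <- 0.07
  eri <- array(0, c(2, 2, 2, 2))
  eri[1, 2, 1, 2] <- eri[2, 1, 1, 2] <- eri[1, 2, 2, 1] <- eri[2, 1, 2, 1] <- t
  d <- (eps_e[1] - eps_e[2]) + (eps_p[1] - eps_p[2])
  expect_equal(ep_mp2_energy(Ce, eps_e, 1, Cp, eps_p, 1, eri),
               2 * t^2 / d, tolerance = 1e-14)
  ## all-zero coupling
  expect_equal(ep_mp2_energy(Ce, eps_e, 1, Cp, eps_p, 1,
                             array(0, c(2, 2, 2, 2))), 0)
  ## dense brute-force loop over every excitation quadruple on a random
  ## 3-orbital toy per species
  set.seed(3)
  ne <- 3; npb <- 3
  eri2 <- array(rnorm(ne^2 * npb^2, sd = 0.05), c(ne, ne, npb, npb))
  eri2 <- eri2 + aperm(eri2, c(2, 1, 3, 4))
  eri2 <- eri2 + aperm(eri2, c(1, 2, 4, 3))
  qe <- qr.Q(qr(matrix(rnorm(9), 3)))
  qp <- qr.Q(qr(matrix(rnorm(9), 3)))
  ee <- sort(rnorm(3)); epp <- sort(rnorm(3))
  E_pkg <- ep_mp2_energy(qe, ee, 1, qp, epp, 1, eri2)
  ## oracle: explicit transform and quadruple loop
  E_ref <- 0
  for (a in 2:3) for (ap in 2:3) {
    tia <- 0
    v <- 0
    for (m in 1:3) for (n in 1:3) for (mp in 1:3) for (np_ in 1:3) {
      v <- v + qe[m, 1] * qe[n, a] * qp[mp, 1] * qp[np_, ap] * eri2[m, n, mp, np_]
    }
    E_ref <- E_ref + 2 * v^2 / (ee[1] - ee[a] + epp[1] - epp[ap])
  }
  expect_equal(E_pkg, E_ref, tolerance = 1e-10)
})

test_that("density-fitted MP2 matches the unfitted route when the fit basis is complete", {
  sys <- tiny_ep_system()
  b <- build_integrals(sys$mol, sys$basis, with_grid = FALSE)
  tm <- neodh:::sph_tmats()
  ## exact fitting set for the s-only product space of both species
  aux_e <- exact_s_product_aux(b$shells_e)
  aux_p <- exact_s_product_aux(b$shells_p)
  aux <- list(l = c(aux_e$l, aux_p$l),
              centers = cbind(aux_e$centers, aux_p$centers),
              exps = c(aux_e$exps, aux_p$exps),
              coefs = c(aux_e$coefs, aux_p$coefs),
              atom_of = c(aux_e$atom_of, aux_p$atom_of),
              nbf = aux_e$nbf + aux_p$nbf)
  class(aux) <- "ShellList"
  M <- neodh:::cpp_eri_2c(aux, tm)
  Lm <- chol(M + diag(1e-12, nrow(M)))
  Be3 <- neodh:::cpp_eri_3c(b$shells_e, aux, tm)
  Bp3 <- neodh:::cpp_eri_3c(b$shells_p, aux, tm)
  ## converged HF orbitals for both species
  scf_e <- neodh:::species_scf(list(S = b$S, h = b$T - b$V, eri = b$eri_ee),
                               occ = 2, a_ex = 1)
  Xp <- neodh:::orthogonalizer(b$Sp)
  cj <- neodh:::cpp_cross_j(b$eri_ep, b$n_e, b$n_p, scf_e$D,
                            matrix(0, b$n_p, b$n_p))
  evp <- eigen(t(Xp) %*% (b$Tp + b$Vp - cj$V2) %*% Xp, symmetric = TRUE)
  ordp <- order(evp$values)
  Cp <- Xp %*% evp$vectors[, ordp]
  eps_p <- evp$values[ordp]
  mp_conv <- electronic_mp2(scf_e$C, scf_e$eps, 1, b$eri_ee)
  mp_df <- electronic_mp2_df(scf_e$C, scf_e$eps, 1, Be3, Lm)
  expect_equal(mp_df$E_os, mp_conv$E_os, tolerance = 1e-8)
  expect_equal(mp_df$E_ss, mp_conv$E_ss, tolerance = 1e-8)
  ep_conv <- ep_mp2_energy(scf_e$C, scf_e$eps, 1, Cp, eps_p, 1, b$eri_ep)
  ep_df <- ep_mp2_energy_df(scf_e$C, scf_e$eps, 1, Cp, eps_p, 1,
                            Be3, Bp3, Lm)
  expect_lt(abs(ep_df - ep_conv), 1e-8)
  expect_lt(ep_conv, 0)
})

test_that("ep-MP2 scales quadratically in the coupling and respects degeneracy invariance", {
  set.seed(5)
  ne <- 3; npb <- 3
  eri <- array(rnorm(81, sd = 0.03), c(ne, ne, npb, npb))
  eri <- eri + aperm(eri, c(2, 1, 3, 4))
  eri <- eri + aperm(eri, c(1, 2, 4, 3))
  Ce <- qr.Q(qr(matrix(rnorm(9), 3)))
  Cp <- qr.Q(qr(matrix(rnorm(9), 3)))
  eps_e <- c(-1, 0.7, 0.7)     # degenerate virtual pair
  eps_p <- c(0.1, 0.9, 1.4)
  E1 <- ep_mp2_energy(Ce, eps_e, 1, Cp, eps_p, 1, eri)
  E2 <- ep_mp2_energy(Ce, eps_e, 1, Cp, eps_p, 1, 2 * eri)
  expect_equal(E2, 4 * E1, tolerance = 1e-10)
  ## unitary mixing within the degenerate electronic virtual block
  th <- 0.6
  R <- diag(3); R[2:3, 2:3] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  E3 <- ep_mp2_energy(Ce %*% R, eps_e, 1, Cp, eps_p, 1, eri)
  expect_equal(E3, E1, tolerance = 1e-10)
  ## degenerate denominator raises an informative error
  expect_error(ep_mp2_energy(Ce, c(0, 0, 1), 1, Cp, c(0, 0, 2), 1, eri),
               "degenerate")
})
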
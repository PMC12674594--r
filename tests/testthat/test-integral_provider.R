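tm <- neodh:::sph_tmats()

test_that("one- and two-particle s integrals match closed-form Gaussians", {
  a <- 0.8; R <- 1.7
  sl <- neodh:::build_shell_list(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, R)),
                                 list(H = list(list(l = 0L, exps = a, coefs = 1))))
  Tf <- neodh:::sph_tmat_full(sl)
  one <- neodh:::cpp_one_ints(sl)
  S <- Tf %*% one$S %*% t(Tf)
  K <- Tf %*% one$T %*% t(Tf)
  expect_equal(diag(S), c(1, 1), tolerance = 1e-12)
  expect_equal(S[1, 2], exp(-a * R^2 / 2), tolerance = 1e-12)
  expect_equal(K[1, 1], 1.5 * a, tolerance = 1e-12)
  V <- Tf %*% neodh:::cpp_nuclear(sl, t(rbind(c(0, 0, 0))), 1) %*% t(Tf)
  expect_equal(V[2, 2], pracma::erf(sqrt(2 * a) * R) / R, tolerance = 1e-10)
  ## two unit Gaussian charge distributions: erf(sqrt(pq/(p+q)) R)/R
  eri <- neodh:::cpp_eri(sl, sl, tm, TRUE, 0)
  p <- 2 * a
  expect_equal(eri[1, 1, 2, 2], pracma::erf(sqrt(p * p / (2 * p)) * R) / R,
               tolerance = 1e-8)
})

test_that("hydrogenic bound-state energies validate each angular momentum", {
  hyd <- function(l) {
    ex <- 5e-4 * (5e3 / 5e-4)^((0:13) / 13)
    shells <- list(H = lapply(ex, function(e) list(l = l, exps = e, coefs = 1)))
    sl <- neodh:::build_shell_list("H", matrix(0, 1, 3), shells)
    Tf <- neodh:::sph_tmat_full(sl)
    one <- neodh:::cpp_one_ints(sl)
    S <- Tf %*% one$S %*% t(Tf)
    H <- Tf %*% one$T %*% t(Tf) -
      Tf %*% neodh:::cpp_nuclear(sl, matrix(0, 3, 1), 1) %*% t(Tf)
    X <- neodh:::orthogonalizer(S)
    min(eigen(t(X) %*% H %*% X, symmetric = TRUE, only.values = TRUE)$values)
  }
  expect_equal(hyd(0L), -0.5, tolerance = 5e-4)
  expect_equal(hyd(1L), -0.125, tolerance = 5e-3)
  expect_equal(hyd(2L), -1 / 18, tolerance = 5e-3)
  expect_equal(hyd(3L), -1 / 32, tolerance = 6e-3)
})

test_that("protonic blocks scale kinetic by the proton mass and carry the repulsive sign", {
  sys <- tiny_ep_system()
  b <- build_integrals(sys$mol, sys$basis, with_grid = FALSE)
  ## same exponents/centers for both species -> T_p = T_e / m_p
  sl <- neodh:::build_shell_list("H", matrix(c(0, 0, 1.6), 1, 3),
                                 list(H = list(list(l = 0L, exps = 6, coefs = 1),
                                               list(l = 0L, exps = 14, coefs = 1))))
  Tf <- neodh:::sph_tmat_full(sl)
  Te <- Tf %*% neodh:::cpp_one_ints(sl)$T %*% t(Tf)
  expect_equal(b$Tp, Te / 1836.15267343, tolerance = 1e-10)
  ## protonic external potential is repulsive towards the positive nucleus
  expect_true(all(diag(b$Vp) > 0))
  ## single proton, single s function: unit overlap
  expect_equal(diag(b$Sp), rep(1, b$n_p), tolerance = 1e-12)
})

test_that("zero quantum protons leaves protonic blocks absent", {
  mol <- parse_xyz(h2o_xyz)
  b <- build_integrals(mol, basis_configuration(electronic = "synSV"),
                       with_grid = FALSE)
  expect_equal(b$n_p, 0L)
  expect_null(b$shells_p)
})

test_that("fitted mixed electron-proton Coulomb reproduces the exact 4-index block", {
  sys <- tiny_ep_system()
  b <- build_integrals(sys$mol, sys$basis, with_grid = FALSE)
  aux <- exact_s_product_aux(b$shells_e)
  auxp <- exact_s_product_aux(b$shells_p)
  aux_all <- list(l = c(aux$l, auxp$l),
                  centers = cbind(aux$centers, auxp$centers),
                  exps = c(aux$exps, auxp$exps),
                  coefs = c(aux$coefs, auxp$coefs),
                  atom_of = c(aux$atom_of, auxp$atom_of),
                  nbf = aux$nbf + auxp$nbf)
  class(aux_all) <- "ShellList"
  M <- neodh:::cpp_eri_2c(aux_all, tm)
  Be <- neodh:::cpp_eri_3c(b$shells_e, aux_all, tm)
  Bp <- neodh:::cpp_eri_3c(b$shells_p, aux_all, tm)
  set.seed(4)
  De <- crossprod(matrix(rnorm(b$n_e^2), b$n_e)) / b$n_e
  Dp <- crossprod(matrix(rnorm(b$n_p^2), b$n_p)) / b$n_p
  ## exact mixed Coulomb energy
  cj <- neodh:::cpp_cross_j(b$eri_ep, b$n_e, b$n_p, De, Dp)
  E_exact <- sum(De * cj$V1)
  ## fitted: (De|P) M^-1 (P|Dp), robust (symmetric) fit
  ve <- crossprod(matrix(Be, b$n_e^2, aux_all$nbf), as.numeric(De))
  vp <- crossprod(matrix(Bp, b$n_p^2, aux_all$nbf), as.numeric(Dp))
  sv <- eigen(M, symmetric = TRUE)
  keep <- sv$values > 1e-10 * max(sv$values)
  Minv <- sv$vectors[, keep] %*% (t(sv$vectors[, keep]) / sv$values[keep])
  E_fit <- as.numeric(t(ve) %*% Minv %*% vp)
  expect_lt(abs(E_fit - E_exact), 1e-6)
})

test_that("validate_bundle reports symmetry defects and grid normalization", {
  sys <- tiny_ep_system()
  b <- build_integrals(sys$mol, sys$basis, grid_level = 3)
  d <- validate_bundle(b)
  expect_lt(d$sym_defect_S, 1e-10)
  expect_lt(d$sym_defect_T, 1e-10)
  expect_true(d$grid_weights_positive)
  expect_lt(d$grid_selfoverlap_max_err, 1e-5)
  b$S[1, 2] <- b$S[1, 2] + 1e-3   # deliberately corrupted
  expect_gt(validate_bundle(b)$sym_defect_S, 1e-4)
})
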
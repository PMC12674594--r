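test_that("DIIS extrapolation solves the Pulay system", {
  F1 <- diag(2)
  ## single entry returned unchanged
  h <- list(list(F = F1, err = matrix(0.3, 2, 2)))
  du <- diis_update(h, 10)
  expect_identical(du$F, F1)
  expect_equal(du$coef, 1)
  ## entry with exactly zero error vector gets full weight
  h0 <- list(list(F = F1, err = matrix(0, 2, 2)))
  expect_identical(diis_update(h0, 10)$F, F1)
  ## two entries with error vectors e and -e: coefficients (1/2, 1/2)
  e <- matrix(c(0.2, -0.1, 0.4, 0.05), 2, 2)
  h2 <- list(list(F = diag(c(1, 0)), err = e),
             list(F = diag(c(0, 1)), err = -e))
  du2 <- diis_update(h2, 10)
  expect_equal(du2$coef, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(du2$F, diag(c(0.5, 0.5)), tolerance = 1e-12)
  ## history truncation
  hl <- rep(list(list(F = F1, err = e)), 15)
  expect_length(diis_update(hl, 10)$history, 10)
  expect_error(diis_update(list(), 10), "empty")
})

test_that("toy2x2 coupled SCF matches the exhaustive orbital-rotation scan", {
  fx <- generate_fixture("toy2x2")
  r <- run_neo_scf(fx$mol, bundle = fx$bundle, functional = "neo-hf",
                   guess = "core")
  bf <- toy2x2_brute_force(fx)
  expect_lt(abs(r$energy - bf$energy), 1e-9)
  ## converged state satisfies the density-matrix invariants
  st <- r$state
  b <- fx$bundle
  expect_lt(max(abs(st$De %*% b$S %*% st$De - 2 * st$De)), 1e-8)
  expect_lt(max(abs(st$Dp %*% b$Sp %*% st$Dp - st$Dp)), 1e-8)
  expect_equal(sum(st$De * b$S), 2, tolerance = 1e-8)
  expect_equal(sum(st$Dp * b$Sp), 1, tolerance = 1e-8)
})

test_that("a single quantum proton is exactly self-interaction-free (J = K)", {
  fx <- generate_fixture("toy2x2")
  r <- run_neo_scf(fx$mol, bundle = fx$bundle, functional = "neo-hf",
                   guess = "core")
  jk <- neodh:::cpp_jk(as.numeric(fx$bundle$eri_pp), 2L, r$state$Dp)
  expect_lt(abs(sum(r$state$Dp * (jk$J - jk$K))), 1e-12)
})

test_that("h2_quantum NEO-DFT run satisfies sign and normalization postconditions", {
  fx <- generate_fixture("h2_quantum")
  r <- run_neo_scf(fx$mol, fx$basis, functional = "neo-b2plyp",
                   grid_level = 3)
  expect_true(r$state$converged)
  expect_lt(r$breakdown$E_epc_dft, 0)
  expect_lte(r$breakdown$E_epc_mp2, 0)
  expect_lt(r$breakdown$E_ec_mp2_os, 0)
  ## converged protonic density integrates to N_p on the grid
  bundle <- r$bundle
  dens_p <- neodh:::grid_density(bundle$phi_p, r$state$Dp)
  expect_equal(sum(bundle$grid$weights * dens_p$rho), 1, tolerance = 1e-6)
  ## and the electronic density to N_e
  dens_e <- neodh:::grid_density(bundle$phi_e, r$state$De)
  expect_equal(sum(bundle$grid$weights * dens_e$rho), 2, tolerance = 1e-6)
})

test_that("total NEO energy is invariant under rigid translation", {
  fx <- generate_fixture("h2_quantum")
  r1 <- run_neo_scf(fx$mol, fx$basis, functional = "neo-hf")
  sh <- c(1.3, -0.7, 2.1)
  mol2 <- quantum_molecule(fx$mol$symbols,
                           sweep(fx$mol$coords, 2, sh, `+`),
                           sweep(fx$mol$quantum_protons, 2, sh, `+`))
  r2 <- run_neo_scf(mol2, fx$basis, functional = "neo-hf")
  expect_lt(abs(r1$energy - r2$energy), 1e-8)
})

test_that("final energy is independent of the DIIS history length", {
  fx <- generate_fixture("toy2x2")
  es <- vapply(c(8L, 10L, 12L), function(len) {
    run_neo_scf(fx$mol, bundle = fx$bundle, functional = "neo-hf",
                guess = "core",
                settings = scf_settings(diis_len = len))$energy
  }, 0)
  expect_lt(max(es) - min(es), 1e-7)
})

test_that("species Fock builders reduce correctly in limiting cases", {
  fx <- generate_fixture("h2_quantum")
  r <- run_neo_scf(fx$mol, fx$basis, functional = "neo-b2plyp")
  b <- r$bundle
  fp <- r$functional
  state <- list(De = r$state$De, Dp = r$state$Dp)
  ## zero protonic density and epc off -> conventional KS Fock
  F0 <- build_electronic_fock(list(De = state$De, Dp = NULL), b, fp,
                              epc_scale = 0)
  Fz <- build_electronic_fock(list(De = state$De,
                                   Dp = matrix(0, b$n_p, b$n_p)), b, fp,
                              epc_scale = 0)
  expect_lt(max(abs(F0 - Fz)), 1e-10)
  ## symmetry
  Ff <- build_electronic_fock(state, b, fp)
  expect_lt(max(abs(Ff - t(Ff))), 1e-10)
  Fp <- build_protonic_fock(state, b, epc_scale = fp$b_epc)
  expect_lt(max(abs(Fp - t(Fp))), 1e-10)
  ## zero electronic density removes the electron-attraction term
  Fp0 <- build_protonic_fock(list(De = matrix(0, b$n_e, b$n_e), Dp = state$Dp),
                             b, epc_scale = 0)
  jk <- neodh:::cpp_jk(b$eri_pp, b$n_p, state$Dp)
  expect_lt(max(abs(Fp0 - (b$Tp + b$Vp + jk$J - jk$K))), 1e-10)
})

test_that("increasing the proton mass drives the NEO energy towards the clamped-proton limit", {
  bdef <- list(H = list(list(l = 0L, exps = 1.3, coefs = 1),
                        list(l = 0L, exps = 0.35, coefs = 1)))
  mol <- quantum_molecule("H", matrix(c(0, 0, 0), 1, 3),
                          quantum_protons = matrix(c(0, 0, 1.4), 1, 3))
  energies <- vapply(c(1, 10, 100), function(k) {
    pb <- protonic_basis_explicit(list(list(l = 0L,
                                            exps = c(4, 9, 20, 45) * sqrt(k))))
    basis <- basis_configuration(electronic = bdef, protonic = pb)
    bundle <- neodh:::build_neo_bundle(mol, basis, grid_level = 2)
    bundle$Tp <- bundle$Tp / k     # extra mass scaling on the kinetic term
    run_neo_scf(mol, basis, functional = "neo-hf", bundle = bundle,
                guess = "core")$energy
  }, 0)
  clamped <- run_rks(quantum_molecule(c("H", "H"),
                                      rbind(c(0, 0, 0), c(0, 0, 1.4))),
                     basis_configuration(electronic = bdef),
                     functional = "hf")$energy
  expect_true(all(diff(energies) < 0))   # monotone trend downward
  expect_true(all(energies > clamped))   # from above
  expect_lt(energies[3] - clamped, 0.02) # approaching the clamped limit
})

test_that("two distant protons repel like point charges", {
  ## two quantum protons far apart: inter-proton Coulomb ~ 1/R
  R <- 20
  mol <- quantum_molecule(character(0), matrix(0, 0, 3),
                          rbind(c(0, 0, 0), c(0, 0, R)), charge = -2L)
  pspec <- protonic_basis_explicit(list(list(l = 0L, exps = c(8, 18))))
  shp <- neodh:::protonic_shell_list(pspec, mol$quantum_protons)
  tm <- neodh:::sph_tmats()
  eri_pp <- neodh:::cpp_eri(shp, shp, tm, TRUE, 0)
  ## one proton in the lowest orbital of each center
  Tf <- neodh:::sph_tmat_full(shp)
  one <- neodh:::cpp_one_ints(shp)
  Sp <- Tf %*% one$S %*% t(Tf)
  n <- shp$nbf
  D1 <- matrix(0, n, n); D2 <- matrix(0, n, n)
  ## normalized single-exponent orbitals on each center
  c1 <- c(1, 0, 0, 0); c2 <- c(0, 0, 1, 0)
  D1 <- tcrossprod(c1); D2 <- tcrossprod(c2)
  jk <- neodh:::cpp_jk(eri_pp, n, D2)
  Ecoul <- sum(D1 * jk$J)
  expect_equal(Ecoul, 1 / R, tolerance = 1e-4)
})
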
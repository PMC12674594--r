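test_that("functional registry returns the published electronic constants", {
  b2 <- get_functional("neo-b2plyp")
  expect_equal(b2$a_ex, 0.53)
  expect_equal(b2$c_ec, 0.27)
  expect_equal(b2$b_epc, 0.875)
  expect_equal(b2$c_epc, 0.125)

  qidh <- get_functional("neo-pbeqidh")
  expect_equal(qidh$a_ex, 3^(-1 / 3), tolerance = 1e-14)
  expect_equal(qidh$a_ex, 0.693361, tolerance = 1e-6)
  expect_equal(qidh$c_ec, 1 / 3, tolerance = 1e-14)
  expect_equal(qidh$b_epc, 0.731)
  expect_equal(qidh$c_epc, 0.269)

  dsd <- get_functional("neo-dsd-pbep86")
  expect_equal(dsd$a_ex, 0.69)
  expect_equal(dsd$c_ec, 0.44)
  expect_equal(dsd$c_eco, 0.52)
  expect_equal(dsd$c_ecs, 0.22)
  expect_equal(dsd$b_epc, 0.806)
  expect_equal(dsd$c_epc, 0.194)

  ## two-parameter optima available under suffixed names, not defaults
  expect_equal(get_functional("neo-b2plyp-2d")$b_epc, 0.660)
  expect_equal(get_functional("neo-b2plyp-2d")$c_epc, 0.875)

  expect_error(get_functional("nope"), "registry")
  ## overrides create new records, registry untouched
  ov <- get_functional("neo-b2plyp", b_epc = 0.5)
  expect_equal(ov$b_epc, 0.5)
  expect_equal(get_functional("neo-b2plyp")$b_epc, 0.875)
})

test_that("energy assembly is the exact linear combination of components", {
  parts <- neodh:::new_energy_breakdown(
    E_ext_ref = -1.0, E_ex_dft = -0.8, E_ex_hf = -0.75, E_ec_dft = -0.3,
    E_ec_mp2_os = -0.2, E_ec_mp2_ss = -0.05, E_epc_dft = -0.04,
    E_epc_mp2 = -0.01, E_disp = -0.002)
  dsd <- get_functional("neo-dsd-pbep86")
  ## hand arithmetic of the DSD form
  Eh <- -1.0 + (1 - 0.69) * (-0.8) + 0.69 * (-0.75) + 0.44 * (-0.3) +
    0.52 * (-0.2) + 0.22 * (-0.05) + 0.806 * (-0.04) + 0.194 * (-0.01) - 0.002
  expect_equal(assemble_energy(parts, dsd), Eh, tolerance = 1e-14)
  b2 <- get_functional("neo-b2plyp")
  Eb <- -1.0 + 0.47 * (-0.8) + 0.53 * (-0.75) + 0.73 * (-0.3) +
    0.27 * (-0.25) + 0.875 * (-0.04) + 0.125 * (-0.01) - 0.002
  expect_equal(assemble_energy(parts, b2), Eb, tolerance = 1e-14)

  ## b_epc = 1, c_epc = 0 reduces to the plain NEO-DFT total (no MP2-ep term)
  red <- get_functional("neo-b2plyp", b_epc = 1, c_epc = 0)
  no_ep <- assemble_energy(parts, red)
  manual <- -1.0 + 0.47 * (-0.8) + 0.53 * (-0.75) + 0.73 * (-0.3) +
    0.27 * (-0.25) + 1.0 * (-0.04) - 0.002
  expect_equal(no_ep, manual, tolerance = 1e-14)

  ## linearity in each slot
  for (slot in c("E_ex_dft", "E_ec_mp2_os", "E_epc_dft")) {
    p2 <- parts; p2[[slot]] <- 2 * parts[[slot]]
    dE <- assemble_energy(p2, b2) - assemble_energy(parts, b2)
    coefs <- c(E_ex_dft = 1 - 0.53, E_ec_mp2_os = 0.27, E_epc_dft = 0.875)
    expect_equal(dE, coefs[[slot]] * parts[[slot]], tolerance = 1e-14)
  }

  ## trivial reduction: everything zero but the reference slot
  p0 <- neodh:::new_energy_breakdown(
    E_ext_ref = -1, E_ex_dft = 0, E_ex_hf = 0, E_ec_dft = 0,
    E_ec_mp2_os = 0, E_ec_mp2_ss = 0, E_epc_dft = 0, E_epc_mp2 = 0,
    E_disp = 0.25)
  expect_equal(assemble_energy(p0, b2), -0.75)

  ## missing component named in the error
  p3 <- parts; p3$E_ec_dft <- NULL
  expect_error(assemble_energy(p3, b2), "E_ec_dft")
})

test_that("dispersion hook is zero when disabled and pairwise otherwise", {
  mol <- parse_xyz(h2o_xyz)
  expect_identical(dispersion_energy(mol, "b3lyp"), 0)
  one <- quantum_molecule("He", matrix(0, 1, 3))
  ct <- data.frame(el1 = "He", el2 = "He", c6 = 1.46, c8 = 14.1)
  dmp <- list(s6 = 1, s8 = 2, a1 = 0.4, a2 = 5.0)
  expect_equal(dispersion_energy(one, "x", "pairwise", ct, dmp), 0)
  two <- quantum_molecule(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 5)))
  R <- 5; r0 <- 0.4 * sqrt(14.1 / 1.46) + 5.0
  Eref <- -1 * 1.46 / (R^6 + r0^6) - 2 * 14.1 / (R^8 + r0^8)
  expect_equal(dispersion_energy(two, "x", "pairwise", ct, dmp), Eref,
               tolerance = 1e-14)
  ## quantum protons count as hydrogens at their centers
  qp <- quantum_molecule("He", matrix(0, 1, 3),
                         quantum_protons = matrix(c(0, 0, 4), 1, 3),
                         charge = 0L)
  cth <- rbind(ct, data.frame(el1 = "He", el2 = "H", c6 = 1.0, c8 = 8.0))
  expect_lt(dispersion_energy(qp, "x", "pairwise", cth, dmp), 0)
})
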
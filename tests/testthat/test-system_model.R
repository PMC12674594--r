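test_that("parse_xyz builds molecules, converts units, validates indices", {
  mol <- parse_xyz(h2o_xyz)
  expect_length(mol$symbols, 3)
  expect_equal(nrow(mol$quantum_protons), 0)
  expect_equal(mol$n_electrons, 10L)
  ## Angstrom -> bohr conversion on the first O coordinate
  expect_equal(mol$coords[1, 3], 0.1173 / 0.529177210903, tolerance = 1e-12)

  molq <- parse_xyz(nh4_xyz, quantum_atom_indices = 2L, charge = 1L)
  expect_length(molq$symbols, 4)
  expect_equal(nrow(molq$quantum_protons), 1)
  expect_equal(molq$n_electrons, 10L)

  expect_error(parse_xyz(nh4_xyz, quantum_atom_indices = 1L),
               "hydrogen")
  expect_error(parse_xyz("2\nbroken\nH 0 0 0"), "fewer atom lines")
  expect_error(parse_xyz("x\ny\nz"), "atom count")
})

test_that("XYZ serialization round-trips coordinates to 1e-10 bohr", {
  mol <- parse_xyz(nh4_xyz, quantum_atom_indices = c(3L, 4L), charge = 1L)
  mol2 <- parse_xyz(write_xyz(mol), quantum_atom_indices = c(4L, 5L),
                    charge = 1L)
  expect_lt(max(abs(mol$coords - mol2$coords)), 1e-10)
  expect_lt(max(abs(mol$quantum_protons - mol2$quantum_protons)), 1e-10)
})

test_that("even-tempered sequences are geometric with exact endpoints", {
  sp <- make_even_tempered(2, 2, 8)
  expect_equal(sp$shells[[1]]$exps, c(2, 8))

  sp10 <- make_even_tempered(10, 2 * sqrt(2), 64)
  expect_equal(sp10$ratio, (64 / (2 * sqrt(2)))^(1 / 9), tolerance = 1e-14)
  expect_equal(sp10$ratio, 1.41421356, tolerance = 1e-6)
  ex <- sp10$shells[[1]]$exps
  expect_true(all(diff(ex) > 0))
  r <- ex[-1] / ex[-length(ex)]
  expect_lt(max(abs(r / r[1] - 1)), 1e-12)

  spdf <- make_even_tempered(10, 2 * sqrt(2), 64, angular_momenta = 0:3)
  nfun <- sum(vapply(spdf$shells, function(s) length(s$exps), 0L))
  expect_equal(nfun, 40L)

  expect_error(make_even_tempered(1, 2, 8), "count")
  expect_error(make_even_tempered(4, -1, 8), "positive")
})

test_that("embedded proton-affinity tables match the printed reference data", {
  pa <- load_dataset("PA21")
  expect_equal(nrow(pa), 21L)
  expect_equal(pa$formula[1], "HCOO-")
  expect_equal(pa$pa_exp_kcal[1], 345.2)
  expect_equal(pa$formula[21], "NO2-")
  expect_equal(pa$pa_exp_kcal[21], 340.1)
  expect_equal(sum(pa$pa_exp_kcal), 6284.2, tolerance = 1e-12)

  ts <- load_dataset("test")
  expect_equal(nrow(ts), 9L)
  expect_equal(ts$formula[1], "CH3CH2O-")
  expect_equal(ts$pa_exp_kcal[1], 378.2)
  expect_equal(sum(ts$pa_exp_kcal), 2790.6, tolerance = 1e-12)

  expect_error(load_dataset("bogus"))
})

test_that("quantum molecule invariants are enforced", {
  expect_error(quantum_molecule("H", matrix(0, 1, 3),
                                quantum_protons = matrix(0, 1, 3)),
               "coincides")
  expect_error(quantum_molecule("He", matrix(0, 1, 3), charge = 5L),
               "negative electron count")
})
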
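test_that("fixtures are deterministic and well-formed", {
  f1 <- generate_fixture("toy2x2")
  f2 <- generate_fixture("toy2x2")
  expect_identical(f1$bundle$eri_ee, f2$bundle$eri_ee)
  expect_identical(f1$he, f2$he)
  expect_equal(f1$bundle$n_e, 2L)
  expect_equal(f1$bundle$n_p, 2L)
  expect_equal(f1$mol$n_electrons, 2L)
  h2 <- generate_fixture("h2_quantum")
  expect_equal(length(h2$mol$symbols), 1L)
  expect_equal(nrow(h2$mol$quantum_protons), 1L)
  expect_equal(h2$mol$charge, 0L)
  expect_identical(write_xyz(h2$mol), write_xyz(generate_fixture("h2_quantum")$mol))
  expect_error(generate_fixture("nope"))
})

test_that("single-point driver serializes a full result record", {
  fx <- generate_fixture("h2_quantum")
  out <- tempfile(fileext = ".json")
  cfg <- run_config(fx$mol, functional = "neo-b2plyp", basis = fx$basis,
                    grid_level = 2, output = out, seed = 7L)
  res <- run_single_point(cfg)
  expect_lt(res$breakdown$E_epc_dft, 0)
  expect_lte(res$breakdown$E_epc_mp2, 0)
  expect_true(file.exists(out))
  rec <- jsonlite::read_json(out)
  expect_equal(rec$functional, "neo-b2plyp")
  expect_true(is.numeric(rec$energy) || is.double(rec$energy))
  expect_equal(rec$config$seed, 7L)
  expect_true(!is.null(rec$breakdown$E_epc_dft))
  ## reduction: b_epc = 1, c_epc = 0 assembly equals the NEO-DFT total for
  ## the same orbitals
  bd <- res$breakdown
  red <- assemble_energy(bd, get_functional("neo-b2plyp", b_epc = 1, c_epc = 0))
  manual <- bd$E_ext_ref + 0.53 * bd$E_ex_hf + 0.47 * bd$E_ex_dft +
    0.73 * bd$E_ec_dft + 0.27 * (bd$E_ec_mp2_os + bd$E_ec_mp2_ss) +
    1.0 * bd$E_epc_dft
  expect_equal(red, manual, tolerance = 1e-10)
})

test_that("benchmark scoring from energy tables matches hand arithmetic", {
  entries <- load_dataset("PA21")
  conv <- 627.5094740631
  rt <- 2.5 * 1.987204259e-3 * 298.15
  ## energies constructed to reproduce the experimental PAs exactly
  tab <- data.frame(label = entries$label,
                    E_A_hartree = 0,
                    E_AH_hartree = -(entries$pa_exp_kcal - rt) / conv)
  bm <- benchmark_dataset("PA21", tab)
  expect_equal(bm$summary$RMSD, 0, tolerance = 1e-10)
  expect_equal(bm$summary$MUE, 0, tolerance = 1e-10)
  expect_true(all(c("carboxylate", "amine", "aromatic", "inorganic") %in%
                  names(bm$by_class)))
  ## 2-entry toy table with known errors
  two <- tab[1:2, ]
  two$E_AH_hartree <- two$E_AH_hartree + c(3, -4) / conv
  bm2 <- benchmark_dataset("PA21", two, subset = entries$label[1:2])
  expect_equal(bm2$summary$RMSD, sqrt(12.5), tolerance = 1e-8)
  expect_equal(bm2$summary$median, 3.5, tolerance = 1e-8)
  ## missing label is reported by name
  expect_error(benchmark_dataset("PA21", tab[-3, ]), "3")
})

test_that("harmonic-route rows are scored through the vibrational correction", {
  entries <- load_dataset("PA21")[1:3, ]
  conv <- 627.5094740631
  rt <- 2.5 * 1.987204259e-3 * 298.15
  tab <- data.frame(label = entries$label, E_A_hartree = 0,
                    E_AH_hartree = -(entries$pa_exp_kcal + 8 - rt) / conv,
                    dE_vib_kcal = 8)
  bm <- benchmark_dataset("PA21", tab, subset = entries$label)
  expect_equal(bm$summary$MUE, 0, tolerance = 1e-8)
})
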
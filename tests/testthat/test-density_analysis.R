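## a normalized s Gaussian "density": rho(r) = N^2 exp(-2a r^2), integral 1
gaussian_density_shells <- function(a = 0.9, center = c(0, 0, 0)) {
  neodh:::build_shell_list("H", matrix(center, 1, 3),
                           list(H = list(list(l = 0L, exps = a, coefs = 1))))
}

test_that("voxel densities integrate and evaluate exactly for a Gaussian", {
  a <- 0.9
  sl <- gaussian_density_shells(a)
  D <- matrix(1, 1, 1)   # one particle in the normalized AO
  g <- density_on_voxels(D, sl, spacing = 0.2, margin = 6)
  expect_equal(g$total, 1, tolerance = 1e-4)
  ## pointwise closed form at a few voxels
  N2 <- (2 * a / pi)^1.5
  for (idx in list(c(10, 12, 15), c(20, 20, 20), c(31, 5, 18))) {
    r <- g$origin + (idx - 1) * g$spacing
    expect_equal(g$values[idx[1], idx[2], idx[3]],
                 N2 * exp(-2 * a * sum(r^2)), tolerance = 1e-10)
  }
  ## enlarging the box changes the integral negligibly
  g2 <- density_on_voxels(D, sl, spacing = 0.2, margin = 9)
  expect_lt(abs(g2$total - g$total), 1e-6)
  ## a box that truncates the density reports its deficit
  expect_warning(density_on_voxels(D, sl, spacing = 0.2, margin = 0.8,
                                   expected_integral = 1),
                 "deficit")
})

test_that("bond-axis profiles conserve charge and detect shifted densities", {
  a <- 1.1
  sl1 <- gaussian_density_shells(a, c(0, 0, 0))
  sl2 <- gaussian_density_shells(a, c(0, 0, 0.4))
  D <- matrix(1, 1, 1)
  box <- rbind(c(-5, 5), c(-5, 5), c(-5, 5.4))
  g1 <- density_on_voxels(D, sl1, box = box, spacing = 0.1)
  g2 <- density_on_voxels(D, sl2, box = box, spacing = 0.1)
  ## identical grids: identically zero profile
  pr0 <- bond_axis_profile(g1, g1, c(0, 0, 0), c(0, 0, 2))
  expect_equal(max(abs(pr0$delta_rho)), 0)
  ## same particle count: profile integral ~ 0
  pr <- bond_axis_profile(g2, g1, c(0, 0, 0), c(0, 0, 2))
  expect_lt(abs(sum(pr$delta_rho)), 1e-3)
  ## slab decomposition is exact (pure reindexing)
  expect_equal(sum(pr$delta_rho),
               sum((g2$values - g1$values)) * 0.1^3, tolerance = 1e-12)
  ## shifted Gaussian: depletion at negative d_H, excess towards the shift,
  ## antisymmetric-like sign change near the midpoint
  neg <- pr$delta_rho[pr$d_H < 0.1]
  pos <- pr$delta_rho[pr$d_H > 0.3 & pr$d_H < 1.5]
  expect_lt(min(neg), 0)
  expect_gt(max(pos), 0)
  ## against direct 1-D numerical integration of the slab integrand:
  ## integral over x,y of the difference is a 1-D Gaussian difference in z
  z <- pr$d_H
  ref <- sqrt(2 * a / pi) * (exp(-2 * a * (z - 0.4)^2) - exp(-2 * a * z^2)) * 0.1
  sel <- abs(z) < 3
  expect_lt(max(abs(pr$delta_rho[sel] - ref[sel])), 5e-4)
  ## grid mismatch error
  g3 <- density_on_voxels(D, sl1, box = box, spacing = 0.2)
  expect_error(bond_axis_profile(g3, g1, c(0, 0, 0), c(0, 0, 2)), "geometry")
})

test_that("multicomponent vs single-component electronic densities differ as expected along the bond axis", {
  ## quantum H2: the single-component density piles onto the point proton,
  ## the multicomponent one delocalizes, so the difference is negative at
  ## the proton position; both integrate to the same electron count
  fx <- generate_fixture("h2_quantum")
  rneo <- run_neo_scf(fx$mol, fx$basis, functional = "neo-b3lyp",
                      grid_level = 2)
  clm <- quantum_molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  rsc <- run_rks(clm, fx$basis, functional = "b3lyp", grid_level = 2)
  box <- rbind(c(-4, 4), c(-4, 4), c(-4, 5.4))
  gneo <- density_on_voxels(rneo$state$De, rneo$bundle$shells_e, box = box,
                            spacing = 0.15)
  ## the classical AO basis spans the same space (H set on both centers)
  gsc <- density_on_voxels(rsc$scf$D, rneo$bundle$shells_e, box = box,
                           spacing = 0.15)
  pr <- bond_axis_profile(gneo, gsc, proton_position = c(0, 0, 1.4),
                          heavy_atom_position = c(0, 0, 0))
  ## charge conservation within box truncation
  expect_lt(abs(sum(pr$delta_rho)), 1e-3)
  ## depletion at the quantum-proton position
  at0 <- pr$delta_rho[which.min(abs(pr$d_H))]
  expect_lt(at0, 0)
})

test_that("cube files round-trip", {
  sl <- gaussian_density_shells(0.8)
  g <- density_on_voxels(matrix(1, 1, 1), sl, spacing = 0.5, margin = 3)
  f <- tempfile(fileext = ".cube")
  write_cube(g, f)
  g2 <- read_cube(f)
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$origin, unname(g$origin), tolerance = 1e-6)
  expect_lt(max(abs(g2$values - g$values)), 1e-6 * max(abs(g$values)))
})
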
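## Voxel-based density analysis: electronic density differences between
## single- and multicomponent calculations, integrated in slabs perpendicular
## to the X-H bond axis.  The distance coordinate d_H is measured from the
## quantum-proton basis center (x = 0), positive towards the heavy atom.

#' Evaluate a one-particle density on a regular voxel grid
#'
#' @param D density matrix in the AO basis
#' @param shells the matching `ShellList`
#' @param box 2-column matrix (min, max) per Cartesian axis in bohr, or NULL
#'   to enclose all shell centers with `margin`
#' @param spacing voxel edge length in bohr (0.05 default)
#' @param margin box margin around the centers when `box` is NULL
#' @param particle tag ("electronic" or "protonic")
#' @param expected_integral optional particle count; a warning reports the
#'   integral deficit when the box misses more than `1e-3` of it
#' @return a `DensityGrid`: origin, spacing, dims, values (3-d array), total
#'   integral
#' @export
density_on_voxels <- function(D, shells, box = NULL, spacing = 0.05,
                              margin = 6, particle = "electronic",
                              expected_integral = NULL) {
  if (is.null(box)) {
    cen <- t(shells$centers)
    box <- cbind(apply(cen, 2, min) - margin, apply(cen, 2, max) + margin)
  }
  ax <- lapply(1:3, function(k) seq(box[k, 1], box[k, 2], by = spacing))
  dims <- vapply(ax, length, 0L)
  tm <- sph_tmats()
  vals <- array(0, dims)
  ## chunk over z-planes to bound memory
  xy <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
  for (iz in seq_len(dims[3])) {
    pts <- cbind(xy, ax[[3]][iz])
    phi <- cpp_ao_grid(shells, pts, tm)
    rho <- rowSums((phi$val %*% D) * phi$val)
    vals[, , iz] <- matrix(rho, dims[1], dims[2])
  }
  total <- sum(vals) * spacing^3
  if (!is.null(expected_integral) &&
      abs(total - expected_integral) > 1e-3) {
    warning(sprintf("voxel box misses density: integral %.6f vs expected %.6f (deficit %.2e)",
                    total, expected_integral, expected_integral - total))
  }
  structure(list(origin = box[, 1], spacing = spacing, dims = dims,
                 values = vals, particle = particle, total = total),
            class = "DensityGrid")
}

#' @export
print.DensityGrid <- function(x, ...) {
  cat(sprintf("DensityGrid (%s): %d x %d x %d voxels, spacing %.3f bohr, integral %.6f\n",
              x$particle, x$dims[1], x$dims[2], x$dims[3], x$spacing, x$total))
  invisible(x)
}

#' Slab-integrated density difference along a bond axis
#'
#' For each slab of width equal to the voxel spacing, perpendicular to the
#' axis from the quantum-proton position towards the heavy atom, returns the
#' integrated density difference `rho_neo - rho_sc`.  Slab assignment is by
#' the projection of each voxel center on the axis; the slab decomposition is
#' a reindexing, so the profile sums exactly to the 3-D integral of the
#' difference.
#'
#' @param rho_neo,rho_sc `DensityGrid`s on identical geometry
#' @param proton_position,heavy_atom_position positions in bohr
#' @return data.frame with `d_H` (slab centers, bohr) and `delta_rho`
#'   (integrated difference per slab)
#' @export
bond_axis_profile <- function(rho_neo, rho_sc, proton_position,
                              heavy_atom_position) {
  if (!isTRUE(all.equal(rho_neo$origin, rho_sc$origin)) ||
      !identical(rho_neo$dims, rho_sc$dims) ||
      rho_neo$spacing != rho_sc$spacing) {
    stop("density grids differ in geometry")
  }
  h <- rho_neo$spacing
  u <- heavy_atom_position - proton_position
  u <- u / sqrt(sum(u^2))
  ax <- lapply(1:3, function(k) rho_neo$origin[k] + h * (seq_len(rho_neo$dims[k]) - 1))
  ## projection of voxel centers on the axis, separable in the three indices
  px <- (ax[[1]] - proton_position[1]) * u[1]
  py <- (ax[[2]] - proton_position[2]) * u[2]
  pz <- (ax[[3]] - proton_position[3]) * u[3]
  proj <- outer(outer(px, py, `+`), pz, `+`)
  slab <- floor(proj / h + 0.5)
  diffv <- (rho_neo$values - rho_sc$values) * h^3
  agg <- tapply(as.numeric(diffv), as.integer(slab), sum)
  data.frame(d_H = (as.integer(names(agg))) * h,
             delta_rho = as.numeric(agg))
}

#' Write a density grid as a Gaussian cube file
#'
#' @param grid a `DensityGrid`
#' @param path output file
#' @param mol optional `QuantumMolecule` for the atom block
#' @export
write_cube <- function(grid, path, mol = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("neodh density grid", paste("particle:", grid$particle)), con)
  nat <- if (is.null(mol)) 0L else length(mol$symbols) + nrow(mol$quantum_protons)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat, grid$origin[1],
                     grid$origin[2], grid$origin[3]), con)
  for (k in 1:3) {
    v <- c(0, 0, 0); v[k] <- grid$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[k], v[1], v[2], v[3]), con)
  }
  if (!is.null(mol)) {
    pos <- rbind(mol$coords, mol$quantum_protons)
    Z <- c(mol$Z, rep(1L, nrow(mol$quantum_protons)))
    for (i in seq_along(Z)) {
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", Z[i], as.numeric(Z[i]),
                         pos[i, 1], pos[i, 2], pos[i, 3]), con)
    }
  }
  ## cube order: x slowest, z fastest
  for (i in seq_len(grid$dims[1])) for (j in seq_len(grid$dims[2])) {
    row <- grid$values[i, j, ]
    writeLines(paste(sprintf("%16.8e", row), collapse = " "), con)
  }
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#' @param path cube file path
#' @return a `DensityGrid`
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3:6]), "[[:space:]]+")
  nat <- as.integer(hdr[[1]][1])
  origin <- as.numeric(hdr[[1]][2:4])
  dims <- vapply(2:4, function(k) as.integer(hdr[[k]][1]), 0L)
  spacing <- as.numeric(hdr[[2]][2])
  start <- 6 + nat + 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:length(lines)]),
                                     "[[:space:]]+")))
  arr <- array(0, dims)
  idx <- 1L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    arr[i, j, ] <- vals[idx:(idx + dims[3] - 1L)]
    idx <- idx + dims[3]
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = arr, particle = "unknown",
                 total = sum(arr) * spacing^3),
            class = "DensityGrid")
}
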
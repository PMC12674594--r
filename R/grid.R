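## Molecular quadrature grid: Treutler-Ahlrichs (M4) radial mapping with
## Gauss-Chebyshev nodes, a Gauss-Legendre x trapezoidal spherical product
## rule (exact for spherical harmonics up to degree 2*ntheta - 1), and Becke
## partition weights with Bragg-radius size adjustment.
##
## Quantum-proton centers participate as additional partition centers with a
## compressed radial mapping so the very localised protonic density is
## resolved.  Named grid levels map to (nrad, ntheta) pairs of increasing
## quality; level 3 is the working default.

grid_params <- function(level) {
  tab <- list(`1` = c(30L, 8L), `2` = c(40L, 11L), `3` = c(55L, 14L),
              `4` = c(70L, 17L), `5` = c(90L, 21L))
  p <- tab[[as.character(level)]]
  if (is.null(p)) stop("unknown grid level: ", level)
  list(nrad = p[1], ntheta = p[2])
}

## radial points/weights for one center; returns r and w with
## sum w_i f(r_i) ~ int_0^inf f(r) r^2 dr
radial_ta_m4 <- function(n, xi) {
  i <- seq_len(n)
  x <- cos(i * pi / (n + 1))
  wgc <- pi / (n + 1) * sin(i * pi / (n + 1))^2
  wx <- wgc / sqrt(1 - x^2)              # d x weights
  a <- xi / log(2)
  r <- a * (1 + x)^0.6 * log(2 / (1 - x))
  drdx <- a * (0.6 * (1 + x)^(-0.4) * log(2 / (1 - x)) + (1 + x)^0.6 / (1 - x))
  keep <- r > 1e-12 & is.finite(drdx)
  list(r = r[keep], w = (wx * r^2 * drdx)[keep])
}

## spherical product rule of given ntheta; returns unit vectors and weights
## summing to 4*pi
angular_product <- function(ntheta) {
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  nphi <- 2L * ntheta
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  u <- cbind(st * cos(phi), st * sin(phi), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(u = u, w = w)
}

#' Build the molecular integration grid
#'
#' @param mol a `QuantumMolecule`
#' @param level grid level 1-5 (3 default)
#' @return list with `points` (n x 3, bohr) and `weights`
#' @export
molecular_grid <- function(mol, level = 3) {
  gp <- grid_params(level)
  cen <- rbind(mol$coords, mol$quantum_protons)
  np <- nrow(mol$quantum_protons)
  nc <- nrow(mol$coords)
  ## quantum-proton centers: a generous partition radius (so the proton cell
  ## owns the region where its sharp density lives), a denser radial mapping
  ## and a higher angular order; classical centers use element defaults with
  ## reduced angular order on the innermost shells
  radii <- c(element_bragg_bohr(mol$Z), rep(1.5, np))
  xi <- c(element_ta_xi(mol$Z), rep(0.6, np))
  nrad <- c(rep(gp$nrad, nc), rep(as.integer(round(1.5 * gp$nrad)), np))
  nth <- c(rep(gp$ntheta, nc), rep(gp$ntheta + 4L, np))
  is_proton <- c(rep(FALSE, nc), rep(TRUE, np))
  pts <- list(); wts <- list(); owner <- list()
  for (ic in seq_len(nrow(cen))) {
    ang_full <- angular_product(nth[ic])
    ang_med <- angular_product(max(6L, nth[ic] %/% 2L))
    rad <- radial_ta_m4(nrad[ic], xi[ic])
    for (k in seq_along(rad$r)) {
      ang <- if (!is_proton[ic] && rad$r[k] < 0.3 * radii[ic]) ang_med
             else ang_full
      p <- ang$u * rad$r[k]
      p <- sweep(p, 2, cen[ic, ], `+`)
      pts[[length(pts) + 1L]] <- p
      wts[[length(wts) + 1L]] <- ang$w * rad$w[k]
      owner[[length(owner) + 1L]] <- rep(ic - 1L, nrow(p))
    }
  }
  pts <- do.call(rbind, pts)
  wts <- unlist(wts)
  owner <- unlist(owner)
  if (nrow(cen) > 1) {
    bw <- cpp_becke_weights(pts, owner, cen, radii)
    wts <- wts * bw
  }
  keep <- wts > 1e-14
  list(points = pts[keep, , drop = FALSE], weights = wts[keep])
}
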
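## Real solid-harmonic transformation matrices.
##
## AO integrals are computed over raw Cartesian monomials x^i y^j z^k e(-a r^2)
## and transformed to real spherical harmonics.  The transform rows are the
## polynomial coefficients of r^l Y_lm (Y_lm orthonormal on the unit sphere),
## obtained by solving an exact interpolation problem on sampled directions;
## r^l Y_lm lies exactly in the degree-l monomial span, so the least-squares
## solve is exact to machine precision.

cart_components <- function(l) {
  out <- list()
  for (ix in seq(l, 0)) for (iy in seq(l - ix, 0)) {
    out[[length(out) + 1L]] <- c(ix, iy, l - ix - iy)
  }
  ## seq(0,0) is fine; but seq(l,0) for l=0 gives 0 only
  do.call(rbind, out)
}

## associated Legendre P_l^m(x) for m = 0..l (Condon-Shortley phase included)
assoc_legendre <- function(l, x) {
  somx2 <- sqrt(pmax(0, 1 - x^2))
  P <- matrix(0, l + 1, length(x))
  for (m in 0:l) {
    pmm <- rep(1, length(x))
    if (m > 0) for (i in 1:m) pmm <- pmm * (-(2 * i - 1)) * somx2
    if (l == m) {
      P[m + 1, ] <- pmm
      next
    }
    pmmp1 <- x * (2 * m + 1) * pmm
    if (l == m + 1) {
      P[m + 1, ] <- pmmp1
      next
    }
    pprev <- pmm
    pcur <- pmmp1
    for (ll in (m + 2):l) {
      pnew <- (x * (2 * ll - 1) * pcur - (ll + m - 1) * pprev) / (ll - m)
      pprev <- pcur
      pcur <- pnew
    }
    P[m + 1, ] <- pcur
  }
  P
}

## real orthonormal spherical harmonics at unit vectors (n x 3)
## order: m = -l, ..., 0, ..., +l
real_sph_harm <- function(l, u) {
  ct <- u[, 3]
  phi <- atan2(u[, 2], u[, 1])
  P <- assoc_legendre(l, ct)
  Y <- matrix(0, nrow(u), 2 * l + 1)
  for (m in 0:l) {
    N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0) {
      Y[, l + 1] <- N * P[1, ]
    } else {
      Y[, l + 1 + m] <- sqrt(2) * N * P[m + 1, ] * cos(m * phi)
      Y[, l + 1 - m] <- sqrt(2) * N * P[m + 1, ] * sin(m * phi)
    }
  }
  Y
}

## (2l+1) x ncart matrix T with r^l Y_lm = sum_c T[m, c] x^i y^j z^k
solid_harmonic_tmat <- function(l) {
  comps <- cart_components(l)
  nc <- nrow(comps)
  ## fixed sampling directions (the solve is exact for any genuine sample);
  ## use a private RNG stream so the caller's seed is untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20240901 + l)
  npt <- 4 * nc + 8
  u <- matrix(stats::rnorm(3 * npt), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  M <- sapply(seq_len(nc), function(ic) {
    u[, 1]^comps[ic, 1] * u[, 2]^comps[ic, 2] * u[, 3]^comps[ic, 3]
  })
  Y <- real_sph_harm(l, u)
  Tm <- t(qr.solve(M, Y))
  Tm[abs(Tm) < 1e-13] <- 0
  Tm
}

## cached list of transforms for l = 0..lmax; element [[l+1]]
sph_tmats <- local({
  cache <- NULL
  function(lmax = 5L) {
    if (is.null(cache) || length(cache) < lmax + 1L) {
      cache <<- lapply(0:lmax, solid_harmonic_tmat)
    }
    cache
  }
})

## block-diagonal full transform (nsph x ncart) for a shell list
sph_tmat_full <- function(shells) {
  tm <- sph_tmats()
  nsph <- sum(2L * shells$l + 1L)
  ncar <- sum((shells$l + 1L) * (shells$l + 2L) / 2L)
  Tf <- matrix(0, nsph, ncar)
  is <- ic <- 0L
  for (k in seq_along(shells$l)) {
    l <- shells$l[k]
    Tl <- tm[[l + 1L]]
    Tf[is + seq_len(2L * l + 1L), ic + seq_len((l + 1L) * (l + 2L) / 2L)] <- Tl
    is <- is + 2L * l + 1L
    ic <- ic + (l + 1L) * (l + 2L) / 2L
  }
  Tf
}
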
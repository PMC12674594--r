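## Electronic exchange-correlation functionals (spin-restricted, closed
## shell).  Every functional is defined once, as an energy density
## e(rho, gamma) per unit volume with gamma = |grad rho|^2; the potentials
## v_rho = de/drho and v_gamma = de/dgamma are generated by Richardson-
## extrapolated central differences of that single definition, so energy and
## potential cannot drift apart.  Densities below a floor are treated as
## vacuum.

.rho_floor <- 1e-12

## ---- LDA pieces ------------------------------------------------------------

e_slater <- function(rho, gam = NULL) {
  cx <- 0.75 * (3 / pi)^(1 / 3)
  -cx * rho^(4 / 3)
}

## VWN correlation, paramagnetic fit; pset "vwn5" or "rpa" (the variant used
## in the Gaussian-style B3LYP)
e_vwn <- function(rho, gam = NULL, pset = "vwn5") {
  p <- switch(pset,
              vwn5 = c(A = 0.0310907, b = 3.72744, c = 12.9352, x0 = -0.10498),
              rpa  = c(A = 0.0310907, b = 13.0720, c = 42.7198, x0 = -0.409286))
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- function(t) t^2 + p["b"] * t + p["c"]
  Q <- sqrt(4 * p["c"] - p["b"]^2)
  atn <- atan(Q / (2 * x + p["b"]))
  X0 <- X(p["x0"])
  ec <- p["A"] * (log(x^2 / X(x)) + 2 * p["b"] / Q * atn -
                  p["b"] * p["x0"] / X0 *
                  (log((x - p["x0"])^2 / X(x)) +
                   2 * (p["b"] + 2 * p["x0"]) / Q * atn))
  unname(rho * ec)
}

## Perdew-Zunger 1981 correlation (local part of P86)
e_pz81 <- function(rho, gam = NULL) {
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  lo <- rs >= 1
  ec <- numeric(length(rs))
  ec[lo] <- -0.1423 / (1 + 1.0529 * sqrt(rs[lo]) + 0.3334 * rs[lo])
  r <- rs[!lo]
  ec[!lo] <- 0.0311 * log(r) - 0.048 + 0.0020 * r * log(r) - 0.0116 * r
  rho * ec
}

## PW92 correlation (unpolarized), local part of PBE
e_pw92 <- function(rho, gam = NULL) {
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  A <- 0.031091; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  den <- 2 * A * (b1 * sqrt(rs) + b2 * rs + b3 * rs^1.5 + b4 * rs^2)
  ec <- -2 * A * (1 + a1 * rs) * log(1 + 1 / den)
  rho * ec
}

## ---- GGA pieces ------------------------------------------------------------

## Becke 88 gradient correction to exchange (correction only)
e_b88corr <- function(rho, gam) {
  beta <- 0.0042
  rs2 <- rho / 2
  x <- (2^(1 / 3)) * sqrt(gam) / rho^(4 / 3)
  ash <- log(x + sqrt(1 + x^2))
  -2 * beta * rs2^(4 / 3) * x^2 / (1 + 6 * beta * x * ash)
}

## Lee-Yang-Parr correlation, closed shell (Miehlich representation with
## rho_a = rho_b = rho/2, gamma_aa = gamma_bb = gamma_ab = gamma/4)
e_lyp <- function(rho, gam) {
  a <- 0.04918; b <- 0.132; cc <- 0.2533; d <- 0.349
  cf <- 0.3 * (3 * pi^2)^(2 / 3)
  r13 <- rho^(-1 / 3)
  den <- 1 + d * r13
  om <- exp(-cc * r13) / den * rho^(-11 / 3)
  del <- cc * r13 + d * r13 / den
  ra <- rho / 2; gaa <- gam / 4; gab <- gam / 4
  gtot <- gam
  t1 <- -a * 4 * ra * ra / (rho * den)
  inner <- ra * ra * (2^(11 / 3) * cf * (ra^(8 / 3) + ra^(8 / 3)) +
                      (47 / 18 - 7 * del / 18) * gtot -
                      (5 / 2 - del / 18) * (gaa + gaa) -
                      ((del - 11) / 9) * (ra * gaa + ra * gaa) / rho) -
           (2 / 3) * rho^2 * gtot +
           ((2 / 3) * rho^2 - ra^2) * gaa +
           ((2 / 3) * rho^2 - ra^2) * gaa
  t1 - a * b * om * inner
}

## PBE exchange
e_pbex <- function(rho, gam) {
  cx <- 0.75 * (3 / pi)^(1 / 3)
  kappa <- 0.804; mu <- 0.2195149727645171
  kf <- (3 * pi^2 * rho)^(1 / 3)
  s2 <- gam / (4 * kf^2 * rho^2)
  fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  -cx * rho^(4 / 3) * fx
}

## PBE correlation (unpolarized)
e_pbec <- function(rho, gam) {
  gma <- (1 - log(2)) / pi^2
  beta <- 0.06672455060314922
  ec_loc <- e_pw92(rho) / rho
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- gam / (4 * ks^2 * rho^2)
  Aden <- exp(-ec_loc / gma) - 1
  A <- (beta / gma) / pmax(Aden, 1e-30)
  num <- 1 + A * t2
  H <- gma * log(1 + beta / gma * t2 * num / (1 + A * t2 + A^2 * t2^2))
  rho * ec_loc + rho * H
}

## Perdew 86 gradient correction to correlation (added to PZ81)
e_p86corr <- function(rho, gam) {
  alpha <- 0.023266; bbet <- 7.389e-6; gmm <- 8.723; dlt <- 0.472
  cinf <- 0.001667 + 0.002568
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  C <- 0.001667 + (0.002568 + alpha * rs + bbet * rs^2) /
       (1 + gmm * rs + dlt * rs^2 + 1e4 * bbet * rs^3)
  gr <- sqrt(gam)
  Phi <- 1.745 * 0.11 * (cinf / C) * gr / rho^(7 / 6)
  exp(-Phi) * C * gam / rho^(4 / 3)
}

## ---- registry of pieces ----------------------------------------------------

.xc_pieces <- list(
  slater  = list(f = e_slater,  gga = FALSE),
  vwn5    = list(f = function(rho, gam) e_vwn(rho, pset = "vwn5"), gga = FALSE),
  vwnrpa  = list(f = function(rho, gam) e_vwn(rho, pset = "rpa"), gga = FALSE),
  pz81    = list(f = e_pz81,    gga = FALSE),
  pw92    = list(f = e_pw92,    gga = FALSE),
  b88corr = list(f = e_b88corr, gga = TRUE),
  lyp     = list(f = e_lyp,     gga = TRUE),
  pbex    = list(f = e_pbex,    gga = TRUE),
  pbec    = list(f = e_pbec,    gga = TRUE),
  p86corr = list(f = e_p86corr, gga = TRUE)
)

## Richardson-extrapolated central difference of f in its k-th argument
## (relative step, so perturbed densities stay positive)
fd_deriv <- function(f, rho, gam, k) {
  h <- 1e-4 * (if (k == 1) rho else gam)
  pert <- function(s, hh) {
    if (k == 1) f(rho + s * hh, gam) else f(rho, gam + s * hh)
  }
  d1 <- (pert(1, h) - pert(-1, h)) / (2 * h)
  d2 <- (pert(1, h / 2) - pert(-1, h / 2)) / h
  (4 * d2 - d1) / 3
}

#' Evaluate an exchange-correlation piece and its potentials on a grid
#'
#' @param name piece name (see `names(neodh:::.xc_pieces)`)
#' @param rho electron density values (closed shell, total)
#' @param gam squared density-gradient values `|grad rho|^2`
#' @return list with `e` (energy density per volume), `vrho`, `vgamma`
#' @keywords internal
xc_eval <- function(name, rho, gam = NULL) {
  pc <- .xc_pieces[[name]]
  if (is.null(pc)) stop("unknown xc piece: ", name)
  live <- rho > .rho_floor
  e <- vr <- numeric(length(rho))
  vg <- numeric(length(rho))
  if (any(live)) {
    r <- rho[live]
    g <- if (pc$gga) pmax(gam[live], 1e-20) else NULL
    e[live] <- pc$f(r, g)
    vr[live] <- fd_deriv(pc$f, r, g, 1)
    if (pc$gga) vg[live] <- fd_deriv(pc$f, r, g, 2)
  }
  list(e = e, vrho = vr, vgamma = vg, gga = pc$gga)
}
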
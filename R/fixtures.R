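## Deterministic fixtures: tiny quantum-proton systems solvable in seconds,
## and a fully hand-set 2x2 integral bundle whose SCF solution can be checked
## against an exhaustive orbital-rotation scan.

#' Generate a named fixture
#'
#' * `h2_quantum`: H2 at 1.4 bohr, one quantum proton, small bases.
#' * `nh4_quantum`: tetrahedral NH4+ (r = 1.93 bohr), one quantum proton.
#' * `hcn_like`: a linear H-C-N test structure with the proton quantized
#'   (a test geometry only; not a benchmark molecule).
#' * `toy2x2`: hand-set `IntegralBundle` with 2 electronic and 2 protonic
#'   basis functions, 1 electron pair + 1 proton; every tensor documented
#'   in-source.  Run it with `run_neo_scf(fx$mol, bundle = fx$bundle,
#'   functional = "neo-hf", guess = "core")`.
#'
#' @param name fixture name
#' @return list with `name`, `mol`, `basis` (and `bundle` for toy2x2)
#' @export
generate_fixture <- function(name = c("h2_quantum", "nh4_quantum",
                                      "hcn_like", "toy2x2")) {
  name <- match.arg(name)
  small_basis <- basis_configuration(electronic = "synSV")
  if (name == "h2_quantum") {
    mol <- quantum_molecule("H", matrix(c(0, 0, 0), 1, 3),
                            quantum_protons = matrix(c(0, 0, 1.4), 1, 3))
    return(list(name = name, mol = mol, basis = small_basis))
  }
  if (name == "nh4_quantum") {
    r <- 1.93
    t <- r / sqrt(3)
    cor <- rbind(c(0, 0, 0), c(t, t, t), c(t, -t, -t), c(-t, t, -t))
    mol <- quantum_molecule(c("N", "H", "H", "H"), cor,
                            quantum_protons = matrix(c(-t, -t, t), 1, 3),
                            charge = 1L)
    return(list(name = name, mol = mol, basis = small_basis))
  }
  if (name == "hcn_like") {
    mol <- quantum_molecule(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 2.18)),
                            quantum_protons = matrix(c(0, 0, -2.01), 1, 3))
    return(list(name = name, mol = mol, basis = small_basis))
  }
  ## toy2x2: orthonormal bases (S = I); all numbers chosen by hand.
  ## Electronic core (bound), protonic core (confining well), and modest
  ## positive-definite Coulomb tensors with full 8-/4-fold symmetry.
  he <- matrix(c(-1.50, -0.20,
                 -0.20, -0.80), 2, 2, byrow = TRUE)
  hp <- matrix(c(0.90, 0.10,
                 0.10, 1.40), 2, 2, byrow = TRUE)
  sym4 <- function(vals) {
    ## vals: function(i,j,k,l) value; build with chemist-notation symmetry
    a <- array(0, c(2, 2, 2, 2))
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
      a[i, j, k, l] <- vals(min(i, j), max(i, j), min(k, l), max(k, l))
    }
    a
  }
  ee_val <- function(i, j, k, l) {
    key <- paste(sort(c(paste0(i, j), paste0(k, l))), collapse = "|")
    switch(key, "11|11" = 0.90, "11|22" = 0.55, "22|22" = 0.80,
           "12|12" = 0.15, "11|12" = 0.05, "12|22" = 0.04, 0)
  }
  pp_val <- function(i, j, k, l) {
    key <- paste(sort(c(paste0(i, j), paste0(k, l))), collapse = "|")
    switch(key, "11|11" = 0.40, "11|22" = 0.30, "22|22" = 0.35,
           "12|12" = 0.05, "11|12" = 0.02, "12|22" = 0.02, 0)
  }
  ep_val <- function(i, j, k, l) {
    ## no bra<->ket symmetry between species: key is (ij, k'l')
    key <- paste0(i, j, "|", k, l)
    switch(key, "11|11" = 0.50, "11|22" = 0.30, "22|11" = 0.35,
           "22|22" = 0.25, "12|11" = 0.04, "12|22" = 0.03,
           "11|12" = 0.03, "22|12" = 0.02, "12|12" = 0.01, 0)
  }
  eri_ee <- sym4(ee_val)
  eri_pp <- sym4(pp_val)
  eri_ep <- sym4(ep_val)
  mol <- quantum_molecule(character(0), matrix(0, 0, 3),
                          quantum_protons = matrix(c(0, 0, 0), 1, 3),
                          charge = -1L)   # 2 electrons, 1 proton
  bundle <- structure(list(
    mol = mol, basis = NULL,
    n_e = 2L, n_p = 2L,
    S = diag(2), T = he, V = matrix(0, 2, 2),
    Sp = diag(2), Tp = hp, Vp = matrix(0, 2, 2),
    eri_ee = eri_ee, eri_pp = eri_pp, eri_ep = eri_ep,
    grid = NULL), class = "IntegralBundle")
  list(name = name, mol = mol, bundle = bundle,
       he = he, hp = hp)
}

#' Exhaustive orbital-rotation oracle for the toy2x2 fixture
#'
#' With 2 basis functions per species and one occupied orbital each, every
#' normalized orbital is `(cos t, sin t)`; the coupled HF energy surface is
#' scanned over both rotation angles and polished with a local optimizer.
#'
#' @param fx the toy2x2 fixture
#' @param n grid points per angle for the initial scan
#' @return list with the minimal energy and the minimizing angles
#' @export
toy2x2_brute_force <- function(fx, n = 181) {
  b <- fx$bundle
  en <- function(te, tp) {
    ce <- c(cos(te), sin(te)); cp <- c(cos(tp), sin(tp))
    De <- 2 * tcrossprod(ce); Dp <- tcrossprod(cp)
    jke <- cpp_jk(as.numeric(b$eri_ee), 2L, De)
    Eee <- 0.5 * sum(De * jke$J) - 0.25 * sum(De * jke$K)
    cj <- cpp_cross_j(as.numeric(b$eri_ep), 2L, 2L, De, Dp)
    Eep <- -sum(De * cj$V1)
    ## a single proton is self-interaction-free (J = K); no p-p term
    sum(De * b$T) + Eee + sum(Dp * b$Tp) + Eep
  }
  ts <- seq(0, pi, length.out = n)
  best <- Inf; arg <- c(0, 0)
  for (te in ts) for (tp in ts) {
    e <- en(te, tp)
    if (e < best) { best <- e; arg <- c(te, tp) }
  }
  opt <- stats::optim(arg, function(t) en(t[1], t[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(energy = opt$value, angles = opt$par, scan_energy = best)
}
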
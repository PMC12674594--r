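## shared builders for small test systems

h2o_xyz <- paste(
  "3", "water",
  "O 0.000000 0.000000 0.117300",
  "H 0.000000 0.757200 -0.469200",
  "H 0.000000 -0.757200 -0.469200", sep = "\n")

nh4_xyz <- paste(
  "5", "ammonium",
  "N 0.0 0.0 0.0",
  "H 0.589 0.589 0.589",
  "H 0.589 -0.589 -0.589",
  "H -0.589 0.589 -0.589",
  "H -0.589 -0.589 0.589", sep = "\n")

## tiny s-only two-center electron system + one quantum proton, with exponents
## small enough for exact density-fitting oracles
tiny_ep_system <- function() {
  mol <- quantum_molecule("He", matrix(c(0, 0, 0), 1, 3),
                          quantum_protons = matrix(c(0, 0, 1.6), 1, 3),
                          charge = 1L)   # 2 electrons, 1 proton
  bdef <- list(He = list(list(l = 0L, exps = 1.2, coefs = 1),
                         list(l = 0L, exps = 0.4, coefs = 1)))
  pspec <- protonic_basis_explicit(list(list(l = 0L, exps = c(6, 14))))
  basis_configuration(electronic = bdef, protonic = pspec)
  list(mol = mol,
       basis = basis_configuration(electronic = bdef, protonic = pspec))
}

## an exact fitting set for s-only products of the electronic/protonic bases
## above: product Gaussians of s shells are s Gaussians at the pair centers
exact_s_product_aux <- function(shells) {
  cen <- t(shells$centers)
  ex <- unlist(shells$exps)
  aux <- list(l = integer(), centers = NULL, exps = list(), coefs = list(),
              atom_of = integer(), nbf = 0L)
  k <- 0L
  for (i in seq_along(shells$l)) for (j in i:length(shells$l)) {
    a <- shells$exps[[i]][1]; b <- shells$exps[[j]][1]
    p <- a + b
    P <- (a * cen[i, ] + b * cen[j, ]) / p
    k <- k + 1L
    aux$l <- c(aux$l, 0L)
    aux$centers <- cbind(aux$centers, P)
    aux$exps[[k]] <- p
    aux$coefs[[k]] <- prim_norm_test(0, p)
    aux$atom_of <- c(aux$atom_of, 1L)
  }
  aux$nbf <- k
  class(aux) <- "ShellList"
  aux
}

prim_norm_test <- function(l, a) sqrt(2 * (2 * a)^(l + 1.5) / gamma(l + 1.5))
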
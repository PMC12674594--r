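## Synthetic electronic basis sets.
##
## Named reference sets (def2-TZVPP etc.) are distributed through external
## basis repositories; this package instead ships self-generating SYNTHETIC
## surrogates of comparable composition, so that everything is reproducible
## from code alone.  Exponents are even-tempered sequences frozen here;
## contraction coefficients are derived at run time from the package's own
## spherically averaged fractional-occupation atomic SCF in the uncontracted
## set (segmented: the core primitives are contracted with the atomic 1s/2s/2p
## coefficients, the outermost primitives stay free).  Users can supply real
## reference sets through `basis_configuration(electronic_file = ...)`.

.synth_recipes <- list(
  synTZ = list(
    H = list(s = list(n = 6, lo = 0.09, hi = 60, ncontr = 4),
             p = list(exps = c(1.45, 0.40)), d = list(exps = 1.0)),
    C = list(s = list(n = 12, lo = 0.16, hi = 50000, ncontr = 9),
             p = list(n = 7, lo = 0.10, hi = 60, ncontr = 5),
             d = list(exps = c(1.10, 0.318)), f = list(exps = 0.76)),
    N = list(s = list(n = 12, lo = 0.22, hi = 70000, ncontr = 9),
             p = list(n = 7, lo = 0.13, hi = 80, ncontr = 5),
             d = list(exps = c(1.65, 0.47)), f = list(exps = 1.09)),
    O = list(s = list(n = 12, lo = 0.27, hi = 90000, ncontr = 9),
             p = list(n = 7, lo = 0.16, hi = 100, ncontr = 5),
             d = list(exps = c(2.31, 0.645)), f = list(exps = 1.43))
  ),
  synSV = list(
    H = list(s = list(n = 4, lo = 0.13, hi = 20, ncontr = 3),
             p = list(exps = 0.8)),
    C = list(s = list(n = 10, lo = 0.18, hi = 25000, ncontr = 8),
             p = list(n = 5, lo = 0.14, hi = 25, ncontr = 4),
             d = list(exps = 0.8)),
    N = list(s = list(n = 10, lo = 0.25, hi = 35000, ncontr = 8),
             p = list(n = 5, lo = 0.18, hi = 30, ncontr = 4),
             d = list(exps = 1.0)),
    O = list(s = list(n = 10, lo = 0.30, hi = 45000, ncontr = 8),
             p = list(n = 5, lo = 0.22, hi = 40, ncontr = 4),
             d = list(exps = 1.2))
  )
)

et_seq <- function(n, lo, hi) {
  r <- (hi / lo)^(1 / (n - 1))
  rev(lo * r^(0:(n - 1)))   # descending (core first)
}

## uncontracted s/p-only definition used for the atomic contraction SCF
uncontracted_sp_def <- function(recipe) {
  shells <- list()
  sx <- et_seq(recipe$s$n, recipe$s$lo, recipe$s$hi)
  for (e in sx) shells[[length(shells) + 1L]] <- list(l = 0L, exps = e, coefs = 1)
  if (!is.null(recipe$p$n)) {
    px <- et_seq(recipe$p$n, recipe$p$lo, recipe$p$hi)
    for (e in px) shells[[length(shells) + 1L]] <- list(l = 1L, exps = e, coefs = 1)
  }
  shells
}

## extract radial coefficients of atomic orbitals for shells of one l
## (SVD over the degenerate m components for robustness)
radial_coefs <- function(C_orb, ao_index_matrix) {
  M <- matrix(C_orb[ao_index_matrix], nrow = nrow(ao_index_matrix))
  if (ncol(M) == 1) return(M[, 1])
  sv <- svd(M)
  v <- sv$u[, 1] * sv$d[1]
  if (sum(v * M[, which.max(colSums(M^2))]) < 0) v <- -v
  v
}

synth_element_def <- function(recipe, symbol) {
  nsex <- recipe$s$n
  npx <- if (!is.null(recipe$p$n)) recipe$p$n else 0L
  unc <- uncontracted_sp_def(recipe)
  at <- atomic_scf_cached(symbol, stats::setNames(list(unc), symbol))
  C <- at$C
  sx <- et_seq(nsex, recipe$s$lo, recipe$s$hi)
  shells <- list()
  ## s contractions: 1s (and 2s for heavier elements) over the core primitives
  s_ao <- seq_len(nsex)                     # s AOs come first by construction
  n_s_orb <- if (element_Z(symbol) > 2) 2L else 1L
  idx_con <- seq_len(recipe$s$ncontr)       # largest exponents
  for (k in seq_len(n_s_orb)) {
    co <- C[s_ao, k][idx_con]
    shells[[length(shells) + 1L]] <- list(l = 0L, exps = sx[idx_con],
                                          coefs = co)
  }
  for (i in setdiff(seq_len(nsex), idx_con)) {
    shells[[length(shells) + 1L]] <- list(l = 0L, exps = sx[i], coefs = 1)
  }
  ## p contraction from the occupied 2p orbital
  if (npx > 0) {
    px <- et_seq(recipe$p$n, recipe$p$lo, recipe$p$hi)
    p_ao <- matrix(nsex + seq_len(3 * npx), nrow = npx, byrow = TRUE)
    pocc <- n_s_orb + 1L                    # first p orbital after 1s/2s
    co <- radial_coefs(C[, pocc], p_ao)
    idx_con <- seq_len(recipe$p$ncontr)
    shells[[length(shells) + 1L]] <- list(l = 1L, exps = px[idx_con],
                                          coefs = co[idx_con])
    for (i in setdiff(seq_len(npx), idx_con)) {
      shells[[length(shells) + 1L]] <- list(l = 1L, exps = px[i], coefs = 1)
    }
  } else if (!is.null(recipe$p$exps)) {
    for (e in recipe$p$exps) {
      shells[[length(shells) + 1L]] <- list(l = 1L, exps = e, coefs = 1)
    }
  }
  ## polarization
  if (npx > 0 && !is.null(recipe$p$exps)) {
    for (e in recipe$p$exps) {
      shells[[length(shells) + 1L]] <- list(l = 1L, exps = e, coefs = 1)
    }
  }
  if (!is.null(recipe$d)) for (e in recipe$d$exps) {
    shells[[length(shells) + 1L]] <- list(l = 2L, exps = e, coefs = 1)
  }
  if (!is.null(recipe$f)) for (e in recipe$f$exps) {
    shells[[length(shells) + 1L]] <- list(l = 3L, exps = e, coefs = 1)
  }
  shells
}

.synth_cache <- new.env(parent = emptyenv())

#' Resolve a built-in synthetic electronic basis by name
#'
#' "synTZ" is the triple-zeta-quality working set (H: 3s2p1d; C/N/O:
#' 5s3p2d1f), "synSV" a faster split-valence set for fixtures.  Both are
#' synthetic surrogates generated by the package itself (see the methods
#' vignette); they are not the def2 reference sets.
#'
#' @param name "synTZ" or "synSV"
#' @param elements element symbols to include
#' @return per-element basis definition list
#' @export
electronic_basis <- function(name = "synTZ",
                             elements = c("H", "C", "N", "O")) {
  rec <- .synth_recipes[[name]]
  if (is.null(rec)) {
    stop("unknown electronic basis '", name,
         "'; built-in: ", paste(names(.synth_recipes), collapse = ", "),
         " (supply reference sets via basis_configuration(electronic_file=))")
  }
  out <- list()
  for (el in elements) {
    if (is.null(rec[[el]])) stop("basis ", name, " has no element ", el)
    key <- paste0(name, "|", el)
    if (is.null(.synth_cache[[key]])) {
      .synth_cache[[key]] <- synth_element_def(rec[[el]], el)
    }
    out[[el]] <- .synth_cache[[key]]
  }
  out
}
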
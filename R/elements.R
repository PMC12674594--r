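## Element lookup: symbols, nuclear charges, Bragg-Slater radii (bohr) used by
## the Becke partitioning, and Treutler-Ahlrichs radial scale factors.

.elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z = 1:18,
  ## Bragg-Slater radii in Angstrom (H set to 0.35 as in Becke's paper)
  bragg_ang = c(0.35, 1.40, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 1.50,
                1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 1.88),
  ## Treutler-Ahlrichs M4 xi parameters
  ta_xi = c(0.8, 0.9, 1.8, 1.4, 1.3, 1.1, 0.9, 0.9, 0.9, 0.9,
            1.4, 1.3, 1.3, 1.2, 1.1, 1.0, 1.0, 1.0),
  stringsAsFactors = FALSE
)

element_Z <- function(sym) {
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) stop("unknown element symbol: ", paste(sym[is.na(i)], collapse = ", "))
  .elements$Z[i]
}

element_symbol <- function(Z) .elements$symbol[match(Z, .elements$Z)]

element_bragg_bohr <- function(Z) {
  angstrom_to_bohr(.elements$bragg_ang[match(Z, .elements$Z)])
}

element_ta_xi <- function(Z) .elements$ta_xi[match(Z, .elements$Z)]
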
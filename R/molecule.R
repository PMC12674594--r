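## Molecular data model: classical point nuclei plus designated quantum
## protons.  Quantum protons carry no point charge in the external potential;
## their positions serve only as protonic basis centers.  All positions are
## stored in bohr.

#' Construct a molecule with designated quantum protons
#'
#' @param symbols character vector of element symbols for the classical nuclei
#' @param coords numeric matrix (n x 3) of classical nuclear positions, bohr
#' @param quantum_protons numeric matrix (np x 3) of quantum-proton basis
#'   centers in bohr (may have zero rows)
#' @param charge net molecular charge
#' @param multiplicity electronic spin multiplicity (only 1 supported by the
#'   SCF solvers)
#' @return an object of class `QuantumMolecule`
#' @export
quantum_molecule <- function(symbols, coords,
                             quantum_protons = matrix(0, 0, 3),
                             charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  quantum_protons <- matrix(as.numeric(quantum_protons), ncol = 3)
  if (length(symbols) != nrow(coords)) {
    stop("symbols and coords disagree in length")
  }
  Z <- element_Z(symbols)
  nel <- sum(Z) + nrow(quantum_protons) - charge
  if (nel < 0) stop("negative electron count")
  ## classical nuclei and quantum protons must be disjoint centers
  if (nrow(coords) > 0 && nrow(quantum_protons) > 0) {
    for (i in seq_len(nrow(quantum_protons))) {
      d <- sqrt(rowSums((coords - matrix(quantum_protons[i, ], nrow(coords), 3,
                                         byrow = TRUE))^2))
      if (any(d < 1e-8)) {
        stop("quantum proton ", i, " coincides with a classical nucleus")
      }
    }
  }
  structure(list(symbols = symbols, Z = Z, coords = coords,
                 quantum_protons = quantum_protons,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 n_electrons = as.integer(nel)),
            class = "QuantumMolecule")
}

#' @export
print.QuantumMolecule <- function(x, ...) {
  cat("QuantumMolecule:", length(x$symbols), "classical nuclei,",
      nrow(x$quantum_protons), "quantum protons, charge", x$charge,
      ",", x$n_electrons, "electrons\n")
  invisible(x)
}

#' Parse an XYZ-format structure into a QuantumMolecule
#'
#' Standard XYZ text (first line atom count, second line comment, then
#' `symbol x y z` in Angstrom).  Atoms listed in `quantum_atom_indices`
#' (1-based, referring to atom lines) must be hydrogens; they are removed from
#' the classical nuclei and become quantum protons at the same position.
#'
#' @param text character scalar or vector of lines with XYZ content
#' @param quantum_atom_indices integer vector of hydrogen atom indices to
#'   treat quantum mechanically
#' @param charge net charge
#' @param multiplicity spin multiplicity
#' @return a `QuantumMolecule` (coordinates converted to bohr)
#' @export
parse_xyz <- function(text, quantum_atom_indices = integer(),
                      charge = 0L, multiplicity = 1L) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  if (length(lines) < 3L) stop("malformed XYZ: fewer than 3 lines")
  nat <- suppressWarnings(as.integer(lines[1]))
  if (is.na(nat)) stop("malformed XYZ: first line is not an atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) < nat) stop("malformed XYZ: fewer atom lines than declared")
  body <- body[seq_len(nat)]
  toks <- strsplit(body, "[[:space:]]+")
  sym <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("malformed XYZ: non-numeric coordinates")
  qi <- as.integer(quantum_atom_indices)
  if (any(qi < 1L | qi > nat)) stop("quantum atom index out of range")
  if (any(sym[qi] != "H")) {
    stop("quantum atom indices must point at hydrogen atoms; got: ",
         paste(unique(sym[qi][sym[qi] != "H"]), collapse = ", "))
  }
  xyz_b <- angstrom_to_bohr(xyz)
  keep <- setdiff(seq_len(nat), qi)
  quantum_molecule(sym[keep], xyz_b[keep, , drop = FALSE],
                   xyz_b[qi, , drop = FALSE], charge, multiplicity)
}

#' Serialize a QuantumMolecule to XYZ text (Angstrom)
#'
#' Quantum protons are written as hydrogen atoms; a comment records which
#' atom lines are quantum.
#' @param mol a `QuantumMolecule`
#' @return character scalar of XYZ text
#' @export
write_xyz <- function(mol) {
  np <- nrow(mol$quantum_protons)
  nat <- length(mol$symbols) + np
  coords <- rbind(mol$coords, mol$quantum_protons)
  sym <- c(mol$symbols, rep("H", np))
  qidx <- if (np > 0) length(mol$symbols) + seq_len(np) else integer()
  cmt <- sprintf("charge=%d mult=%d quantum=%s", mol$charge, mol$multiplicity,
                 paste(qidx, collapse = ","))
  ang <- bohr_to_angstrom(coords)
  lines <- c(as.character(nat), cmt,
             sprintf("%-3s %18.12f %18.12f %18.12f", sym,
                     ang[, 1], ang[, 2], ang[, 3]))
  paste(lines, collapse = "\n")
}

## all charged centers seen by the electrons (classical nuclei only: quantum
## protons act through their density, not as point charges)
classical_charges <- function(mol) {
  list(q = as.numeric(mol$Z), cen = t(mol$coords))
}

## classical nuclear repulsion energy (quantum protons excluded)
nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- e + mol$Z[i] * mol$Z[j] / sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
  }
  e
}
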
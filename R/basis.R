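## Gaussian basis model.
##
## A "basis definition" is a named list (by element symbol, or "proton") whose
## elements are lists of shells `list(l =, exps =, coefs =)`, with contraction
## coefficients referring to radially normalised primitives.  A "shell list"
## is the flattened structure handed to the C++ integral kernels, with
## primitive norms and the contracted-AO normalisation folded into the
## coefficients.

## radial norm of a primitive solid-harmonic Gaussian r^l Y_lm e(-a r^2)
prim_norm <- function(l, a) sqrt(2 * (2 * a)^(l + 1.5) / gamma(l + 1.5))

## contracted self-overlap with coefficients over normalised primitives
contracted_selfoverlap <- function(l, exps, coefs) {
  cn <- coefs * prim_norm(l, exps)
  S <- 0
  for (p in seq_along(exps)) for (q in seq_along(exps)) {
    S <- S + cn[p] * cn[q] * gamma(l + 1.5) / (2 * (exps[p] + exps[q])^(l + 1.5))
  }
  S
}

#' Build a shell list by placing per-element shells at given centers
#'
#' @param symbols element labels (match names of `basis_def`)
#' @param centers n x 3 matrix of positions (bohr)
#' @param basis_def named list of per-element shell definitions
#' @return a shell-list object used by the integral provider
#' @keywords internal
build_shell_list <- function(symbols, centers, basis_def) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  l <- integer(); cen <- NULL; exps <- list(); coefs <- list()
  atom_of <- integer(); shell_l <- integer()
  for (i in seq_along(symbols)) {
    ed <- basis_def[[symbols[i]]]
    if (is.null(ed)) stop("no basis for element ", symbols[i])
    for (sh in ed) {
      l <- c(l, sh$l)
      cen <- cbind(cen, centers[i, ])
      raw <- sh$coefs * prim_norm(sh$l, sh$exps)
      raw <- raw / sqrt(contracted_selfoverlap(sh$l, sh$exps, sh$coefs))
      exps[[length(exps) + 1L]] <- as.numeric(sh$exps)
      coefs[[length(coefs) + 1L]] <- as.numeric(raw)
      atom_of <- c(atom_of, i)
    }
  }
  nsph <- sum(2L * l + 1L)
  structure(list(l = as.integer(l), centers = cen, exps = exps, coefs = coefs,
                 atom_of = atom_of, nbf = nsph),
            class = "ShellList")
}

#' @export
print.ShellList <- function(x, ...) {
  cat("ShellList:", length(x$l), "shells,", x$nbf, "spherical AOs\n")
  invisible(x)
}

n_basis <- function(shells) shells$nbf

## ---------------------------------------------------------------------------
## Even-tempered sequences and protonic basis specifications

#' Even-tempered protonic basis specification
#'
#' Exponents form a geometric sequence from `alpha_min` to `alpha_max`
#' inclusive, repeated for every requested angular momentum.
#'
#' @param count exponents per shell (>= 2)
#' @param alpha_min,alpha_max positive exponent bounds, `alpha_min < alpha_max`
#' @param angular_momenta integer vector of l values (0 = s, 1 = p, ...)
#' @return a `ProtonicBasisSpec` with mode "even_tempered"
#' @export
make_even_tempered <- function(count, alpha_min, alpha_max,
                               angular_momenta = 0L) {
  if (count < 2) stop("even-tempered count must be >= 2")
  if (alpha_min <= 0 || alpha_max <= 0) stop("exponents must be positive")
  if (alpha_min >= alpha_max) stop("alpha_min must be < alpha_max")
  r <- (alpha_max / alpha_min)^(1 / (count - 1))
  ex <- alpha_min * r^(0:(count - 1))
  shells <- lapply(as.integer(angular_momenta),
                   function(l) list(l = l, exps = ex))
  structure(list(mode = "even_tempered", shells = shells,
                 count = count, alpha_min = alpha_min, alpha_max = alpha_max,
                 ratio = r),
            class = "ProtonicBasisSpec")
}

#' Explicit protonic basis specification
#' @param shells list of `list(l =, exps =)` with strictly increasing positive
#'   exponents within each shell
#' @export
protonic_basis_explicit <- function(shells) {
  for (sh in shells) {
    if (any(sh$exps <= 0)) stop("exponents must be strictly positive")
    if (is.unsorted(sh$exps, strictly = TRUE)) {
      stop("exponents must be strictly increasing within a shell")
    }
  }
  structure(list(mode = "explicit", shells = shells),
            class = "ProtonicBasisSpec")
}

#' Resolve a named protonic orbital basis
#'
#' The published PB4-F2 / PB6-F exponent sets are not shipped with the
#' package; when a named set cannot be resolved from a user-supplied file the
#' package substitutes a documented even-tempered synthetic surrogate of
#' comparable composition (s/p/d/f shells spanning the typical protonic
#' exponent range), and records the substitution in the returned object.
#'
#' @param name basis name ("PB4-F2", "PB6-F") or "synthetic"
#' @param file optional path to a basis file (neodh/NWChem-style text) whose
#'   "proton" element block supplies the exponents
#' @return a `ProtonicBasisSpec`
#' @export
protonic_basis <- function(name = "PB4-F2", file = NULL) {
  if (!is.null(file)) {
    def <- read_basis_file(file)
    blk <- def[["proton"]]
    if (is.null(blk)) blk <- def[["H"]]
    if (is.null(blk)) stop("basis file has no proton/H block")
    sp <- protonic_basis_explicit(lapply(blk, function(s)
      list(l = s$l, exps = sort(s$exps))))
    sp$name <- name
    sp$surrogate <- FALSE
    return(sp)
  }
  ## synthetic surrogate: even-tempered s/p/d/f around the proton
  sp <- structure(list(
    mode = "named", name = name, surrogate = TRUE,
    shells = c(lapply(list(
      list(l = 0L, n = 6L, lo = 2.0, hi = 32.0),
      list(l = 1L, n = 4L, lo = 5.0, hi = 25.0)),
      function(d) {
        r <- (d$hi / d$lo)^(1 / (d$n - 1))
        list(l = d$l, exps = d$lo * r^(0:(d$n - 1)))
      }),
      list(list(l = 2L, exps = c(8.0, 20.0)),
           list(l = 3L, exps = 12.0)))),
    class = "ProtonicBasisSpec")
  sp
}

## default protonic density-fitting basis: even-tempered 10s10p10d10f with
## exponents from 2*sqrt(2) to 64
protonic_fitting_default <- function() {
  make_even_tempered(10L, 2 * sqrt(2), 64, angular_momenta = 0:3)
}

## shells for np protons at given centers from a ProtonicBasisSpec
## (protonic sets are uncontracted: one shell per exponent)
protonic_shell_list <- function(spec, centers) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  shells <- list()
  for (s in spec$shells) {
    for (e in s$exps) {
      shells[[length(shells) + 1L]] <- list(l = s$l, exps = e, coefs = 1)
    }
  }
  build_shell_list(rep("proton", nrow(centers)), centers,
                   list(proton = shells))
}

## ---------------------------------------------------------------------------
## Basis file reader (NWChem-style text, the format used by basis-set
## exchanges):  blocks "<El>  <SHELL>" followed by rows of exponent and one or
## more contraction columns; multiple columns become separate shells.

#' Read a basis-set definition from an NWChem-style text file
#' @param path file path
#' @return named list (by element) of shells `list(l, exps, coefs)`
#' @export
read_basis_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(BASIS|END|basis|end)", lines)]
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)
  out <- list()
  cur_el <- NULL; cur_l <- NULL; rows <- list()
  flush_block <- function() {
    if (is.null(cur_el) || length(rows) == 0) return()
    m <- do.call(rbind, rows)
    for (col in 2:ncol(m)) {
      keep <- abs(m[, col]) > 0
      if (!any(keep)) next
      out[[cur_el]][[length(out[[cur_el]]) + 1L]] <<-
        list(l = cur_l, exps = m[keep, 1], coefs = m[keep, col])
    }
  }
  for (ln in lines) {
    tk <- strsplit(ln, "[[:space:]]+")[[1]]
    if (toupper(tk[1]) %in% names(lmap) && length(tk) == 1) {
      ## bare shell label continuing current element
      flush_block()
      rows <- list(); cur_l <- lmap[[toupper(tk[1])]]
    } else if (length(tk) == 2 && toupper(tk[2]) %in% names(lmap) &&
               is.na(suppressWarnings(as.numeric(tk[1])))) {
      flush_block()
      rows <- list()
      cur_el <- tk[1]
      if (is.null(out[[cur_el]])) out[[cur_el]] <- list()
      cur_l <- lmap[[toupper(tk[2])]]
    } else {
      v <- suppressWarnings(as.numeric(gsub("[dD]", "e", tk)))
      if (anyNA(v)) stop("cannot parse basis line: ", ln)
      rows[[length(rows) + 1L]] <- v
    }
  }
  flush_block()
  out
}

## ---------------------------------------------------------------------------

#' Basis configuration for a multicomponent calculation
#'
#' @param electronic name of the electronic orbital basis ("synTZ", "synSV")
#'   or a basis definition list; named reference sets (def2-TZVPP, ...) can be
#'   supplied through `electronic_file`
#' @param protonic a `ProtonicBasisSpec` (default: the synthetic PB4-F2
#'   surrogate)
#' @param electronic_file optional NWChem-style basis file resolving
#'   `electronic` by name
#' @param electronic_fitting,protonic_fitting optional fitting sets for
#'   density-fitted paths ("auto" generates an even-tempered fit)
#' @return a `BasisConfiguration`
#' @export
basis_configuration <- function(electronic = "synTZ",
                                protonic = protonic_basis(),
                                electronic_file = NULL,
                                electronic_fitting = "auto",
                                protonic_fitting = protonic_fitting_default()) {
  if (is.character(electronic) && nchar(electronic) == 0) {
    stop("electronic basis name must be non-empty")
  }
  structure(list(electronic = electronic, protonic = protonic,
                 electronic_file = electronic_file,
                 electronic_fitting = electronic_fitting,
                 protonic_fitting = protonic_fitting),
            class = "BasisConfiguration")
}

## resolve the electronic basis definition of a configuration
resolve_electronic_basis <- function(basis_cfg,
                                     elements = c("H", "C", "N", "O")) {
  el <- basis_cfg$electronic
  if (is.list(el)) return(el)
  if (!is.null(basis_cfg$electronic_file)) {
    return(read_basis_file(basis_cfg$electronic_file))
  }
  electronic_basis(el, elements)
}
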
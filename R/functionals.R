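## Functional parameter registry and pure-arithmetic energy assembly.
##
## The registry stores, for every functional, the self-consistent
## exchange-correlation composition (weighted pieces entering the SCF
## potential), the exact-exchange fraction, the MP2 coefficients, and the
## electron-proton correlation admixture {b_epc, c_epc}.  EnergyBreakdown
## slots hold *unweighted* components, so the total energy of any assembly is
## a pure linear combination over the breakdown.

.functional_registry <- local({
  lam <- 3^(-1 / 3)
  reg <- list(
    hf = list(family = "hybrid", a_ex = 1, xc_scf = list(),
              ex_dft = character(), ec_dft = character()),
    ## hybrids (electronic); B3LYP in the VWN5 convention, b3lyp3 the
    ## Gaussian-style VWN-RPA variant
    b3lyp = list(family = "hybrid", a_ex = 0.20,
                 xc_scf = list(slater = 0.80, b88corr = 0.72,
                               vwn5 = 0.19, lyp = 0.81),
                 ex_dft = character(), ec_dft = character()),
    b3lyp3 = list(family = "hybrid", a_ex = 0.20,
                  xc_scf = list(slater = 0.80, b88corr = 0.72,
                                vwnrpa = 0.19, lyp = 0.81),
                  ex_dft = character(), ec_dft = character()),
    pbe0 = list(family = "hybrid", a_ex = 0.25,
                xc_scf = list(pbex = 0.75, pbec = 1.0),
                ex_dft = character(), ec_dft = character()),
    pbe = list(family = "hybrid", a_ex = 0,
               xc_scf = list(pbex = 1.0, pbec = 1.0),
               ex_dft = character(), ec_dft = character()),
    blyp = list(family = "hybrid", a_ex = 0,
                xc_scf = list(slater = 1.0, b88corr = 1.0, lyp = 1.0),
                ex_dft = character(), ec_dft = character()),
    ## double hybrids: E = Eref + (1-a_ex)ExDFT + a_ex ExHF
    ##                   + (1-c_ec)EcDFT + c_ec EcMP2 (B2PLYP/QIDH form)
    b2plyp = list(family = "b2plyp", a_ex = 0.53, c_ec = 0.27,
                  ex_dft = c("slater", "b88corr"), ec_dft = "lyp"),
    `dsd-pbep86` = list(family = "dsd", a_ex = 0.69, c_ec = 0.44,
                        c_eco = 0.52, c_ecs = 0.22,
                        ex_dft = "pbex", ec_dft = c("pz81", "p86corr")),
    pbeqidh = list(family = "b2plyp", a_ex = lam, c_ec = 1 / 3,
                   ex_dft = "pbex", ec_dft = "pbec")
  )
  ## derive the SCF composition of the double hybrids
  for (nm in c("b2plyp", "dsd-pbep86", "pbeqidh")) {
    fp <- reg[[nm]]
    xw <- list()
    for (p in fp$ex_dft) xw[[p]] <- (1 - fp$a_ex)
    cw <- if (fp$family == "dsd") fp$c_ec else (1 - fp$c_ec)
    for (p in fp$ec_dft) xw[[p]] <- cw
    reg[[nm]]$xc_scf <- xw
  }
  ## NEO variants: admixtures from the 1-parameter optimization; the
  ## 2-parameter optima are registered under the "-2d" suffix
  neo <- function(base, b, cc) {
    fp <- reg[[base]]
    fp$b_epc <- b; fp$c_epc <- cc
    fp
  }
  reg[["neo-b2plyp"]]        <- neo("b2plyp", 0.875, 0.125)
  reg[["neo-dsd-pbep86"]]    <- neo("dsd-pbep86", 0.806, 0.194)
  reg[["neo-pbeqidh"]]       <- neo("pbeqidh", 0.731, 0.269)
  reg[["neo-b2plyp-2d"]]     <- neo("b2plyp", 0.660, 0.875)
  reg[["neo-dsd-pbep86-2d"]] <- neo("dsd-pbep86", 0.635, 0.801)
  reg[["neo-pbeqidh-2d"]]    <- neo("pbeqidh", 0.542, 1.000)
  reg[["neo-b3lyp"]]         <- neo("b3lyp", 1.0, 0.0)
  reg[["neo-pbe0"]]          <- neo("pbe0", 1.0, 0.0)
  reg[["neo-hf"]]            <- neo("hf", 0.0, 0.0)
  for (nm in names(reg)) {
    reg[[nm]]$name <- nm
    if (is.null(reg[[nm]]$b_epc)) reg[[nm]]$b_epc <- 0
    if (is.null(reg[[nm]]$c_epc)) reg[[nm]]$c_epc <- 0
    if (is.null(reg[[nm]]$c_ec)) reg[[nm]]$c_ec <- 0
    if (is.null(reg[[nm]]$c_eco)) {
      reg[[nm]]$c_eco <- reg[[nm]]$c_ec
      reg[[nm]]$c_ecs <- reg[[nm]]$c_ec
    }
    reg[[nm]]$disp_tag <- nm
    class(reg[[nm]]) <- "FunctionalParams"
  }
  reg
})

#' Look up a functional in the registry
#'
#' Known names: hf, b3lyp, b3lyp3, pbe0, pbe, blyp, b2plyp, dsd-pbep86,
#' pbeqidh and the NEO variants neo-b2plyp, neo-dsd-pbep86, neo-pbeqidh
#' (1-parameter admixture defaults), their "-2d" two-parameter counterparts,
#' neo-b3lyp, neo-pbe0, neo-hf.  Overriding an admixture returns a new
#' parameter record; the registry itself is immutable.
#'
#' @param name registry name (case-insensitive)
#' @param b_epc,c_epc optional overrides of the epc-17.2 / MP2
#'   electron-proton correlation admixture
#' @return a `FunctionalParams`
#' @export
get_functional <- function(name, b_epc = NULL, c_epc = NULL) {
  fp <- .functional_registry[[tolower(name)]]
  if (is.null(fp)) {
    stop("unknown functional '", name, "'; registry: ",
         paste(names(.functional_registry), collapse = ", "))
  }
  if (!is.null(b_epc)) fp$b_epc <- b_epc
  if (!is.null(c_epc)) fp$c_epc <- c_epc
  stopifnot(fp$a_ex >= 0, fp$a_ex <= 1, fp$b_epc >= 0, fp$b_epc <= 1,
            fp$c_epc >= 0, fp$c_epc <= 1)
  fp
}

#' @export
print.FunctionalParams <- function(x, ...) {
  cat("FunctionalParams:", x$name, " family", x$family,
      sprintf(" a_ex=%.6f c_ec=%.4f (os %.4f ss %.4f) b_epc=%.4f c_epc=%.4f\n",
              x$a_ex, x$c_ec, x$c_eco, x$c_ecs, x$b_epc, x$c_epc))
  invisible(x)
}

#' List all registered functionals
#' @return data.frame of names and key coefficients
#' @export
list_functionals <- function() {
  do.call(rbind, lapply(.functional_registry, function(fp) {
    data.frame(name = fp$name, family = fp$family, a_ex = fp$a_ex,
               c_ec = fp$c_ec, c_eco = fp$c_eco, c_ecs = fp$c_ecs,
               b_epc = fp$b_epc, c_epc = fp$c_epc)
  }))
}

#' Assemble the total energy from an EnergyBreakdown
#'
#' Pure arithmetic over separately stored (unweighted) components, following
#' the functional family: B2PLYP/PBEQIDH-style
#' `Eref + (1-a)ExDFT + a ExHF + (1-c)EcDFT + c EcMP2 + b_epc EpcDFT +
#' c_epc EpcMP2`, the DSD form with `c_ec EcDFT + c_os EosMP2 + c_ss EssMP2`,
#' and the plain hybrid composition for non-double-hybrids.  The dispersion
#' slot is added unscaled.
#'
#' @param parts an `EnergyBreakdown`
#' @param params a `FunctionalParams`
#' @return total energy in hartree
#' @export
assemble_energy <- function(parts, params) {
  need <- function(slot) {
    v <- parts[[slot]]
    if (is.null(v)) stop("EnergyBreakdown is missing component: ", slot)
    v
  }
  e <- need("E_ext_ref")
  disp <- if (is.null(parts$E_disp)) 0 else parts$E_disp
  if (params$family == "hybrid") {
    e <- e + params$a_ex * need("E_ex_hf") + need("E_xc_scf")
  } else if (params$family == "b2plyp") {
    e <- e + (1 - params$a_ex) * need("E_ex_dft") +
      params$a_ex * need("E_ex_hf") +
      (1 - params$c_ec) * need("E_ec_dft") +
      params$c_ec * (need("E_ec_mp2_os") + need("E_ec_mp2_ss"))
  } else if (params$family == "dsd") {
    e <- e + (1 - params$a_ex) * need("E_ex_dft") +
      params$a_ex * need("E_ex_hf") +
      params$c_ec * need("E_ec_dft") +
      params$c_eco * need("E_ec_mp2_os") + params$c_ecs * need("E_ec_mp2_ss")
  } else stop("unknown family: ", params$family)
  if (params$b_epc != 0 || params$c_epc != 0 || !is.null(parts$E_epc_dft)) {
    if (params$b_epc != 0) e <- e + params$b_epc * need("E_epc_dft")
    if (params$c_epc != 0) e <- e + params$c_epc * need("E_epc_mp2")
  }
  e + disp
}

#' Pairwise dispersion correction hook
#'
#' Evaluates a D3(BJ)-type pairwise correction
#' `-sum_AB [ s6 C6/(R^6 + f(R0)^6) + s8 C8/(R^8 + f(R0)^8) ]` from a
#' user-supplied coefficient table.  The CN-interpolated reference C6 data of
#' the published D3 model are distributed with external dispersion codes and
#' are not shipped here, so the default provider is "none", which returns
#' exactly zero; supplying `provider = "pairwise"` with a coefficient table
#' enables the correction.  Quantum protons count as hydrogen atoms at their
#' basis-center positions.
#'
#' @param mol a `QuantumMolecule`
#' @param functional_tag functional name selecting damping parameters
#' @param provider "none" (default) or "pairwise"
#' @param coef_table data.frame with columns el1, el2, c6, c8 (atomic units)
#'   for "pairwise"
#' @param damping named list with s6, s8, a1, a2 for "pairwise"
#' @return dispersion energy in hartree (0 when the provider is disabled)
#' @export
dispersion_energy <- function(mol, functional_tag, provider = "none",
                              coef_table = NULL, damping = NULL) {
  if (identical(provider, "none")) return(0)
  if (!identical(provider, "pairwise")) stop("unknown dispersion provider")
  if (is.null(coef_table) || is.null(damping)) {
    stop("pairwise dispersion needs coef_table and damping parameters")
  }
  sym <- c(mol$symbols, rep("H", nrow(mol$quantum_protons)))
  pos <- rbind(mol$coords, mol$quantum_protons)
  n <- length(sym)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    row <- coef_table[(coef_table$el1 == sym[i] & coef_table$el2 == sym[j]) |
                      (coef_table$el1 == sym[j] & coef_table$el2 == sym[i]), ]
    if (nrow(row) == 0) stop("no C6/C8 for pair ", sym[i], "-", sym[j])
    c6 <- row$c6[1]; c8 <- row$c8[1]
    R <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    r0 <- damping$a1 * sqrt(c8 / c6) + damping$a2
    e <- e - damping$s6 * c6 / (R^6 + r0^6) - damping$s8 * c8 / (R^8 + r0^8)
  }
  e
}
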
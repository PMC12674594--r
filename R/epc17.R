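## epc-17.2 electron-proton correlation: an LDA-type functional of the two
## one-particle densities,
##     E_epc = - int rho_e rho_p / (a - b sqrt(rho_e rho_p) + c rho_e rho_p)
## with (a, b, c) = (2.35, 2.4, 6.6).  The denominator is positive for all
## nonnegative densities whenever b^2 < 4ac, so the energy is never positive.

#' epc-17.2 parameter set
#' @param a,b,c dimensionless functional parameters
#' @return an `EPCParams` list
#' @export
epc_params <- function(a = 2.35, b = 2.4, c = 6.6) {
  if (b^2 >= 4 * a * c) {
    stop("epc denominator not positive definite: need b^2 < 4ac")
  }
  structure(list(a = a, b = b, c = c), class = "EPCParams")
}

.epc_floor <- 1e-14

check_epc_densities <- function(rho_e, rho_p) {
  if (length(rho_e) != length(rho_p)) stop("density arrays differ in length")
  if (any(rho_e < -1e-12) || any(rho_p < -1e-12)) {
    stop("negative density beyond tolerance passed to epc functional")
  }
  list(e = ifelse(rho_e < .epc_floor, 0, rho_e),
       p = ifelse(rho_p < .epc_floor, 0, rho_p))
}

#' epc-17.2 correlation energy on a quadrature grid
#'
#' @param rho_e,rho_p electronic and protonic density values on the grid
#' @param weights quadrature weights
#' @param params an `EPCParams`
#' @return correlation energy in hartree (non-positive)
#' @export
epc_energy <- function(rho_e, rho_p, weights, params = epc_params()) {
  d <- check_epc_densities(rho_e, rho_p)
  g <- d$e * d$p
  den <- params$a - params$b * sqrt(g) + params$c * g
  sum(weights * (-g / den))
}

#' Pointwise epc-17.2 potentials
#'
#' Functional derivatives of the epc energy density with respect to the
#' electronic and protonic densities.  With g = rho_e * rho_p and
#' D = a - b sqrt(g) + c g, `d e / d g = -(a - b/2 sqrt(g)) / D^2`, and the
#' potentials follow by the chain rule.
#'
#' @inheritParams epc_energy
#' @return list with `v_e` and `v_p` grid vectors
#' @export
epc_potentials <- function(rho_e, rho_p, params = epc_params()) {
  d <- check_epc_densities(rho_e, rho_p)
  g <- d$e * d$p
  den <- params$a - params$b * sqrt(g) + params$c * g
  dfdg <- -(params$a - 0.5 * params$b * sqrt(g)) / den^2
  v_e <- dfdg * d$p
  v_p <- dfdg * d$e
  v_e[d$p == 0] <- 0
  v_p[d$e == 0] <- 0
  list(v_e = v_e, v_p = v_p)
}
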
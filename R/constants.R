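#' Physical constants and unit conversions
#'
#' Energies are in eV throughout, temperatures in kelvin, inverse
#' temperatures beta in 1/eV, and magnetic moments in Bohr magnetons
#' (g = 2, so the z-moment of one orbital is (n_up - n_dn) muB).
#'
#' @name units
NULL

#' Boltzmann constant in eV per kelvin
#' @export
k_B <- 8.617333e-5

#' Convert temperature to inverse temperature
#'
#' @param T_kelvin temperature in K (strictly positive)
#' @return beta in 1/eV
#' @export
beta_from_T <- function(T_kelvin) {
  stopifnot(is.numeric(T_kelvin), all(T_kelvin > 0))
  1 / (k_B * T_kelvin)
}

#' Convert inverse temperature to temperature
#'
#' @param beta inverse temperature in 1/eV (strictly positive)
#' @return temperature in K
#' @export
T_from_beta <- function(beta) {
  stopifnot(is.numeric(beta), all(beta > 0))
  1 / (k_B * beta)
}
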
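#' Bohr magneton in eV per tesla
#' @export
mu_B_eV_per_T <- 5.7883818e-5

#' Two-band model for the UV magnetic circular dichroism of deoxy-heme
#'
#' Minimal orbital-selective model of the pi -> pi* transitions of the
#' porphyrin layer: a filled bonding pi level about 3 eV below the Fermi
#' level, a nearly half-filled antibonding pi1* band and a nearly empty
#' pi2* band about 0.3 eV higher, both of width ~0.3 eV. Left-circularly
#' polarized light drives pi -> pi1* and right-circularly polarized light
#' drives pi -> pi2*; because the pi1* spin polarization is locked
#' antiparallel to the Fe(3d) moment by the antiferromagnetic Fe-host
#' coupling, the two bands acquire opposite, Curie-law (1/T) circular
#' polarizations, which produces the anomalous peak-then-shallow-dip
#' line shape.
#'
#' @param E_pi depth of the bonding pi level below the Fermi level (eV,
#'   positive number, default 3.0)
#' @param E1,E2 pi1* and pi2* band centers relative to the Fermi level
#'   (eV, defaults 0.0 and +0.3; requires E2 >= E1)
#' @param w1,w2 band widths (Gaussian sigma, eV, default 0.3)
#' @param f1,f2 band fillings in [0, 1] (defaults 0.5 and 0.0: nearly
#'   half-filled pi1*, nearly empty pi2*)
#' @param A overall dipole strength (arbitrary units)
#' @param coupling_sign +1 for antiferromagnetic Fe-pi1* coupling (the
#'   deoxy-heme case), -1 for the conventional sign
#' @param g_eff effective g-factor entering the thermal polarization
#' @return object of class `mcd_band_model`
#' @export
mcd_band_model <- function(E_pi = 3.0, E1 = 0.0, E2 = 0.3,
                           w1 = 0.3, w2 = 0.3, f1 = 0.5, f2 = 0.0,
                           A = 1, coupling_sign = +1, g_eff = 2) {
  stopifnot(w1 > 0, w2 > 0, f1 >= 0, f1 <= 1, f2 >= 0, f2 <= 1,
            E2 >= E1, abs(coupling_sign) == 1)
  structure(list(E_pi = E_pi, E1 = E1, E2 = E2, w1 = w1, w2 = w2,
                 f1 = f1, f2 = f2, A = A, coupling_sign = coupling_sign,
                 g_eff = g_eff),
            class = "mcd_band_model")
}

#' Thermal band polarization
#'
#' p = sign * tanh(g_eff muB B / (2 k_B T)): the Curie-law carrier of the
#' temperature dependence of the MCD amplitude, linear in B/T in the
#' paramagnetic regime. Flipping the coupling sign models the
#' effective-negative-g-factor behavior of the pi* states.
#'
#' @param T_kelvin temperature in K (> 0)
#' @param B_tesla applied field in tesla
#' @param coupling_sign +1 or -1
#' @param g_eff effective g-factor (default 2)
#' @return polarization in [-1, 1]
#' @export
band_polarization <- function(T_kelvin, B_tesla, coupling_sign = +1,
                              g_eff = 2) {
  stopifnot(T_kelvin > 0)
  coupling_sign * tanh(g_eff * mu_B_eV_per_T * B_tesla /
                         (2 * k_B * T_kelvin))
}

band_shape <- function(E, E0, w, lineshape) {
  if (lineshape == "gaussian") stats::dnorm(E, E0, w)
  else (w / pi) / ((E - E0)^2 + w^2)
}

#' MCD and absorption spectrum of the two-band model
#'
#' Delta_eps(E) = A p [(1 - f1) G(E; E_pi + E1, w1)
#'                     - (1 - f2) G(E; E_pi + E2, w2)],
#' eps(E) = A [(1 - f1) G1 + (1 - f2) G2], with G a unit-area line shape.
#' The absorption is temperature independent; all T and B dependence
#' enters through the polarization p.
#'
#' @param model an `mcd_band_model`
#' @param T_kelvin temperature in K
#' @param B_tesla applied field in tesla
#' @param grid energy grid in eV (default spans both bands +- 3 widths)
#' @param lineshape "gaussian" (default) or "lorentzian"
#' @param polarization optional externally supplied polarization (e.g.
#'   derived from a QMC Fe-pi1* correlation), overriding the thermal
#'   tanh form
#' @return data frame of class `mcd_spectrum` with columns `E`, `dEps`,
#'   `eps`; attributes `T_kelvin`, `B_tesla`, `p`
#' @export
mcd_spectrum <- function(model, T_kelvin, B_tesla, grid = NULL,
                         lineshape = c("gaussian", "lorentzian"),
                         polarization = NULL) {
  stopifnot(inherits(model, "mcd_band_model"))
  lineshape <- match.arg(lineshape)
  wmax <- max(model$w1, model$w2)
  if (is.null(grid))
    grid <- seq(model$E_pi + model$E1 - 3 * wmax,
                model$E_pi + model$E2 + 3 * wmax, length.out = 601)
  p <- if (is.null(polarization))
    band_polarization(T_kelvin, B_tesla, model$coupling_sign, model$g_eff)
  else polarization
  G1 <- band_shape(grid, model$E_pi + model$E1, model$w1, lineshape)
  G2 <- band_shape(grid, model$E_pi + model$E2, model$w2, lineshape)
  dEps <- model$A * p * ((1 - model$f1) * G1 - (1 - model$f2) * G2)
  eps <- model$A * ((1 - model$f1) * G1 + (1 - model$f2) * G2)
  out <- data.frame(E = grid, dEps = dEps, eps = eps)
  attr(out, "T_kelvin") <- T_kelvin
  attr(out, "B_tesla") <- B_tesla
  attr(out, "p") <- p
  class(out) <- c("mcd_spectrum", "data.frame")
  out
}

#' Classify an MCD line shape
#'
#' Orders the signs of the extrema of Delta_eps(E) along increasing
#' energy: a positive peak followed by a dip is the anomalous deoxy-HbA
#' shape; a dip followed by a peak is the conventional shape; a spectrum
#' with |Delta_eps| below tolerance everywhere is "null". The result is
#' invariant under overall amplitude scaling.
#'
#' @param spectrum an `mcd_spectrum` (or data frame with `E`, `dEps`)
#' @param tol relative tolerance for the null classification
#' @return one of "anomalous", "normal", "null"
#' @export
classify_lineshape <- function(spectrum, tol = 1e-10) {
  stopifnot(nrow(spectrum) >= 3)
  d <- spectrum$dEps[order(spectrum$E)]
  scale <- max(abs(d))
  eps_ref <- max(abs(spectrum$eps))
  if (!is.finite(scale) || scale <= tol * max(eps_ref, 1)) return("null")
  d <- d / scale
  # interior local extrema with non-negligible magnitude
  i <- 2:(length(d) - 1)
  is_ext <- (d[i] - d[i - 1]) * (d[i + 1] - d[i]) <= 0 & abs(d[i]) > 0.05
  ext_sign <- sign(d[i][is_ext])
  ext_sign <- ext_sign[ext_sign != 0]
  keep <- c(TRUE, diff(ext_sign) != 0)  # collapse plateaus
  ext_sign <- ext_sign[keep]
  if (length(ext_sign) == 0) return("null")
  if (ext_sign[1] > 0) "anomalous" else "normal"
}

#' MCD peak amplitude versus temperature
#'
#' Tracks the amplitude of the leading extremum across temperatures; in
#' the Curie regime (g muB B << k_B T) the amplitude scales as 1/T.
#'
#' @param model an `mcd_band_model`
#' @param B_tesla applied field in tesla
#' @param T_list temperatures in K
#' @param grid optional energy grid passed to `mcd_spectrum`
#' @return data frame with columns `T_kelvin`, `amplitude`
#' @export
amplitude_vs_T <- function(model, B_tesla, T_list, grid = NULL) {
  amp <- vapply(T_list, function(Tk) {
    sp <- mcd_spectrum(model, Tk, B_tesla, grid = grid)
    max(abs(sp$dEps))
  }, 0)
  data.frame(T_kelvin = T_list, amplitude = amp)
}
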
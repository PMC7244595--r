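#' Multi-orbital Anderson impurity model
#'
#' Defines the Hamiltonian of a cluster with correlated impurity orbitals
#' (the five Fe(3d) orbitals for heme) hybridized with a set of
#' noninteracting host molecular-orbital levels:
#' a one-body part with host energies \eqn{\epsilon_m}, impurity energies
#' \eqn{\epsilon_{d\nu}}, hybridizations \eqn{V_{m\nu}}, all measured
#' against the chemical potential \eqn{\mu}, plus density-density Coulomb
#' terms on the impurity: intra-orbital \eqn{U n_{\nu\uparrow}
#' n_{\nu\downarrow}}, inter-orbital opposite spin \eqn{U' = U - 2J} and
#' inter-orbital parallel spin \eqn{U'' = U' - J}. Only the longitudinal
#' (density-density) part of the Hund coupling is kept; spin-flip and
#' pair-hopping terms are excluded, so total \eqn{S_z} is conserved.
#'
#' The host levels are taken as already diagonal (molecular-orbital
#' eigenstates), so the one-body matrix has arrowhead structure: no
#' host-host or impurity-impurity off-diagonal elements. Hybridizations
#' are real.
#'
#' @param host_energies numeric vector of host level energies (eV)
#' @param impurity_energies numeric vector of impurity level energies (eV);
#'   length 5 for heme, any length >= 1 in general
#' @param hybridization matrix of couplings, rows = host states,
#'   columns = impurity orbitals (eV)
#' @param U intra-orbital Coulomb repulsion (eV, >= 0)
#' @param J Hund coupling (eV, 0 <= J <= U/2; a warning is issued if
#'   U - 3J < 0, which would make the parallel-spin channel attractive)
#' @param mu chemical potential (eV)
#' @param n_target target total electron number for chemical-potential
#'   tuning (optional)
#' @param host_labels,orbital_labels optional character labels (e.g.
#'   "pi1*" host states; "xy", "xz", "yz", "z2", "x2y2" orbitals)
#' @return an object of class `anderson_model`
#' @examples
#' m <- anderson_model(host_energies = 1, impurity_energies = -1,
#'                     hybridization = 0.5, U = 2, J = 0)
#' one_body_matrix(m)
#' @export
anderson_model <- function(host_energies, impurity_energies, hybridization,
                           U, J = 0, mu = 0, n_target = NULL,
                           host_labels = NULL, orbital_labels = NULL) {
  host_energies <- as.numeric(host_energies)
  impurity_energies <- as.numeric(impurity_energies)
  hybridization <- as.matrix(hybridization)
  storage.mode(hybridization) <- "double"
  n_host <- length(host_energies)
  n_orb <- length(impurity_energies)
  if (n_orb < 1) stop("at least one impurity orbital is required")
  if (!all(is.finite(c(host_energies, impurity_energies, hybridization, U, J, mu))))
    stop("all model parameters must be finite")
  if (nrow(hybridization) != n_host || ncol(hybridization) != n_orb)
    stop(sprintf(
      "hybridization must be %d x %d (host states x impurity orbitals), got %d x %d",
      n_host, n_orb, nrow(hybridization), ncol(hybridization)))
  if (U < 0) stop("U must be >= 0")
  if (J < 0) stop("J must be >= 0")
  if (J > U / 2)
    stop("J must satisfy J <= U/2 so that U' = U - 2J >= 0")
  if (U - 3 * J < 0)
    warning("U - 3J < 0: the parallel-spin channel is attractive and cannot ",
            "be decoupled with a real Hubbard-Stratonovich constant")
  if (!is.null(host_labels)) stopifnot(length(host_labels) == n_host)
  if (!is.null(orbital_labels)) stopifnot(length(orbital_labels) == n_orb)
  structure(
    list(host_energies = host_energies,
         impurity_energies = impurity_energies,
         hybridization = hybridization,
         U = U, J = J, Uprime = U - 2 * J, Udprime = U - 3 * J,
         mu = mu, n_target = n_target,
         n_host = n_host, n_orb = n_orb,
         host_labels = host_labels, orbital_labels = orbital_labels),
    class = "anderson_model")
}

#' @export
print.anderson_model <- function(x, ...) {
  cat(sprintf("Anderson impurity model: %d impurity orbital(s), %d host state(s)\n",
              x$n_orb, x$n_host))
  cat(sprintf("  U = %g eV, J = %g eV (U' = %g, U'' = %g), mu = %g eV\n",
              x$U, x$J, x$Uprime, x$Udprime, x$mu))
  if (!is.null(x$n_target))
    cat(sprintf("  target electron number: %g\n", x$n_target))
  cat(sprintf("  host window: [%g, %g] eV; |V| up to %g eV\n",
              min(x$host_energies), max(x$host_energies),
              max(abs(x$hybridization))))
  invisible(x)
}

#' Replace the chemical potential of a model
#' @param model an `anderson_model`
#' @param mu new chemical potential (eV)
#' @return the model with `mu` replaced
#' @export
set_mu <- function(model, mu) {
  stopifnot(inherits(model, "anderson_model"), is.finite(mu))
  model$mu <- mu
  model
}

#' Imaginary-time grid for the discrete-time QMC
#'
#' The interval \eqn{[0, \beta)} is divided into `L` slices of width
#' `dtau` = beta/L. A warning is issued when `dtau * max(U, U', U'')`
#' exceeds 0.5, where Trotter errors become sizeable.
#'
#' @param beta inverse temperature in 1/eV (give either `beta` or
#'   `T_kelvin`)
#' @param L number of time slices (>= 2); give either `L` or `dtau`
#' @param T_kelvin temperature in K, alternative to `beta`
#' @param dtau slice width in 1/eV, alternative to `L` (L is rounded up)
#' @param model optional `anderson_model` used for the Trotter-size warning
#' @return an object of class `tau_grid` with fields `beta`, `L`, `dtau`
#' @export
tau_grid <- function(beta = NULL, L = NULL, T_kelvin = NULL, dtau = NULL,
                     model = NULL) {
  if (is.null(beta)) {
    if (is.null(T_kelvin)) stop("give either beta or T_kelvin")
    beta <- beta_from_T(T_kelvin)
  }
  stopifnot(is.finite(beta), beta > 0)
  if (is.null(L)) {
    if (is.null(dtau)) stop("give either L or dtau")
    L <- as.integer(ceiling(beta / dtau - 1e-9))
  }
  L <- as.integer(L)
  if (L < 2) stop("L must be >= 2")
  dtau <- beta / L
  if (!is.null(model)) {
    wmax <- max(model$U, model$Uprime, model$Udprime)
    if (dtau * wmax > 0.5)
      warning(sprintf("dtau * max interaction = %.3g > 0.5: expect sizeable Trotter error",
                      dtau * wmax))
  }
  structure(list(beta = beta, L = L, dtau = dtau), class = "tau_grid")
}

#' @export
print.tau_grid <- function(x, ...) {
  cat(sprintf("imaginary-time grid: beta = %g 1/eV (T = %.4g K), L = %d, dtau = %g\n",
              x$beta, T_from_beta(x$beta), x$L, x$dtau))
  invisible(x)
}

#' Interaction pair table with Hubbard-Stratonovich constants
#'
#' Enumerates every density-density interacting pair of impurity
#' spin-orbitals together with its coupling W and the discrete
#' Hubbard-Stratonovich constant \eqn{\lambda} defined by
#' \eqn{\cosh\lambda = e^{\Delta\tau W / 2}}:
#' \itemize{
#'   \item intra-orbital \eqn{(\nu\uparrow, \nu\downarrow)} with W = U
#'     (`n_orb` pairs),
#'   \item inter-orbital opposite spin \eqn{(\nu\sigma, \nu'\bar\sigma)},
#'     \eqn{\nu > \nu'}, with W = U' = U - 2J (`n_orb (n_orb-1)` pairs),
#'   \item inter-orbital same spin \eqn{(\nu\sigma, \nu'\sigma)},
#'     \eqn{\nu > \nu'}, with W = U'' = U' - J (`n_orb (n_orb-1)` pairs).
#' }
#' For 5 orbitals this gives 45 pairs. Spins are coded 1 = up, 2 = down.
#'
#' @param model an `anderson_model`
#' @param grid a `tau_grid`
#' @return data frame with columns `orb_a`, `spin_a`, `orb_b`, `spin_b`,
#'   `W`, `lambda`, and attribute `dtau`
#' @export
pair_table <- function(model, grid) {
  stopifnot(inherits(model, "anderson_model"), inherits(grid, "tau_grid"))
  n <- model$n_orb
  rows <- list()
  add <- function(oa, sa, ob, sb, W) {
    rows[[length(rows) + 1L]] <<- data.frame(
      orb_a = oa, spin_a = sa, orb_b = ob, spin_b = sb, W = W)
  }
  for (v in seq_len(n)) add(v, 1L, v, 2L, model$U)
  if (n >= 2) {
    for (v in 2:n) for (vp in 1:(v - 1)) {
      add(v, 1L, vp, 2L, model$Uprime)   # nu up, nu' down
      add(v, 2L, vp, 1L, model$Uprime)   # nu down, nu' up
      add(v, 1L, vp, 1L, model$Udprime)  # parallel up
      add(v, 2L, vp, 2L, model$Udprime)  # parallel down
    }
  }
  tab <- do.call(rbind, rows)
  if (any(tab$W < 0))
    stop("attractive channel (W < 0): unsupported by the Ising decoupling")
  tab$lambda <- acosh(exp(grid$dtau * tab$W / 2))
  attr(tab, "dtau") <- grid$dtau
  class(tab) <- c("pair_table", "data.frame")
  tab
}

# One-body shift that converts U n_a n_b into the particle-hole symmetric
# form U (n_a - 1/2)(n_b - 1/2) used by the discrete decoupling:
# each spin-orbital picks up + sum_p W_p / 2 over the pairs containing it.
# Spin symmetry makes the shift orbital-diagonal and spin-independent.
hartree_shift <- function(model) {
  n <- model$n_orb
  model$impurity_energies + (model$U + (n - 1) * (model$Uprime + model$Udprime)) / 2
}
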
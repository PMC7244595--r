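#' One-body matrix of an Anderson model
#'
#' Assembles the single-particle Hamiltonian (per spin) in the basis
#' (host states, then impurity orbitals), with all energies measured from
#' the chemical potential. Host states are molecular-orbital eigenstates,
#' so the matrix is an arrowhead: diagonal host block, diagonal impurity
#' block, and the hybridization V in the off-diagonal host-impurity block.
#'
#' @param model an `anderson_model`
#' @return symmetric matrix of size `n_host + n_orb`
#' @export
one_body_matrix <- function(model) {
  stopifnot(inherits(model, "anderson_model"))
  nh <- model$n_host; no <- model$n_orb
  n <- nh + no
  H <- matrix(0, n, n)
  diag(H) <- c(model$host_energies, model$impurity_energies) - model$mu
  if (nh > 0) {
    H[seq_len(nh), nh + seq_len(no)] <- model$hybridization
    H[nh + seq_len(no), seq_len(nh)] <- t(model$hybridization)
  }
  H
}

# Thermal weight e^{-tau E} / (1 + e^{-beta E}) evaluated without ever
# forming e^{beta |E|}; valid for 0 <= tau <= beta.
fermi_weight <- function(E, tau, beta) {
  w <- numeric(length(E))
  pos <- E >= 0
  w[pos] <- exp(-tau * E[pos]) / (1 + exp(-beta * E[pos]))
  w[!pos] <- exp((beta - tau) * E[!pos]) / (1 + exp(beta * E[!pos]))
  w
}

# Fermi occupation with overflow guard.
fermi_fn <- function(E, beta) fermi_weight(E, beta, beta)

#' Noninteracting thermal occupations
#'
#' Diagonalizes the one-body matrix and evaluates Fermi-function
#' occupations; used to seed chemical-potential tuning.
#'
#' @param model an `anderson_model`
#' @param T_kelvin temperature in K (or give `beta`)
#' @param beta inverse temperature in 1/eV
#' @return list with `site_occupations` (per spin, host sites then
#'   impurity orbitals), `impurity_occupations` (per spin), and `N_total`
#'   counting both spins
#' @export
noninteracting_density <- function(model, T_kelvin = NULL, beta = NULL) {
  if (is.null(beta)) beta <- beta_from_T(T_kelvin)
  es <- eigen(one_body_matrix(model), symmetric = TRUE)
  f <- fermi_fn(es$values, beta)
  n_site <- drop((es$vectors^2) %*% f)
  list(site_occupations = n_site,
       impurity_occupations = n_site[model$n_host + seq_len(model$n_orb)],
       N_total = 2 * sum(f))
}

#' Bath (noninteracting) Green's function on the imaginary-time grid
#'
#' Builds the imaginary-time propagator
#' \eqn{g_{ab}(\tau) = -\langle T c_a(\tau) c_b^\dagger(0)\rangle} of the
#' full one-body problem from its eigen-decomposition, folding every host
#' level into the impurity block. The impurity block is returned as an
#' (n_orb L) x (n_orb L) matrix G0 with orbital-major layout (index
#' (nu-1) L + l, slices l = 1..L at tau_l = (l-1) dtau) and the
#' antiperiodic convention g(tau - beta) = -g(tau); equal-time entries are
#' the tau -> 0+ limit. The propagator is spin-independent at zero field.
#'
#' @param model an `anderson_model`
#' @param grid a `tau_grid`
#' @return object of class `bath_g0`: list with `g0` (impurity-block
#'   matrix), `eig` (one-body eigen-decomposition), `grid`, and index
#'   bookkeeping used by the host-observable embedding
#' @export
bath_g0 <- function(model, grid) {
  stopifnot(inherits(model, "anderson_model"), inherits(grid, "tau_grid"))
  es <- eigen(one_body_matrix(model), symmetric = TRUE)
  g0 <- g_block_matrix(es, grid, model$n_host + seq_len(model$n_orb))
  structure(list(g0 = g0, eig = es, grid = grid,
                 n_host = model$n_host, n_orb = model$n_orb),
            class = "bath_g0")
}

# Propagator slab g_{ab}(tau) for site subsets; rows/cols are site indices
# into the one-body basis. tau in (-beta, beta]; tau = 0 means 0+.
g_tau_sites <- function(es, beta, tau, rows, cols) {
  Cr <- es$vectors[rows, , drop = FALSE]
  Cc <- es$vectors[cols, , drop = FALSE]
  if (tau > 0 || tau == 0) {
    w <- fermi_weight(es$values, tau, beta)
    -(Cr %*% (t(Cc) * w))
  } else {
    w <- fermi_weight(es$values, tau + beta, beta)
    Cr %*% (t(Cc) * w)
  }
}

# Full slice-resolved block matrix G0[(a,i),(b,j)] = g_ab(tau_i - tau_j)
# for the given site subset, orbital-major layout.
g_block_matrix <- function(es, grid, sites) {
  L <- grid$L; dtau <- grid$dtau; beta <- grid$beta
  ns <- length(sites)
  # g values for all slice differences d = -(L-1) .. (L-1)
  gd <- array(0, dim = c(ns, ns, 2 * L - 1))
  for (d in -(L - 1):(L - 1))
    gd[, , d + L] <- g_tau_sites(es, beta, d * dtau, sites, sites)
  G0 <- matrix(0, ns * L, ns * L)
  idx <- outer(seq_len(L), seq_len(L), `-`) + L  # i - j + L
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    vals <- gd[a, b, ]
    G0[(a - 1) * L + seq_len(L), (b - 1) * L + seq_len(L)] <-
      matrix(vals[idx], L, L)
  }
  G0
}
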
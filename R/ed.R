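#' Exact diagonalization of small Anderson clusters
#'
#' Builds and diagonalizes the full Fock-space Hamiltonian of a small
#' cluster (host levels plus impurity orbitals). Because only the
#' longitudinal part of the Hund coupling is kept, both the total electron
#' number and the total S_z are conserved, and the Hamiltonian is
#' block-diagonal in (N_up, N_dn); the blocked path exploits this, and a
#' dense unblocked path over the full 4^n_sites space is retained for
#' cross-validation. ED is the correctness anchor for every QMC estimator,
#' not a production solver: the default cap is 6 sites (12 spin-orbitals).
#'
#' Fock states are encoded as integers with up-spin occupations in bits
#' 0..n-1 and down-spin occupations in bits n..2n-1 (site order: host
#' states first, then impurity orbitals).
#'
#' @param model an `anderson_model`
#' @param max_sites refuse clusters above this size (default 6)
#' @param blocked use (N_up, N_dn) symmetry blocking (default) or one
#'   dense diagonalization of the full Fock space
#' @return object of class `ed_spectrum`: per-block eigenvalues,
#'   eigenvectors and basis-state encodings
#' @export
ed_spectrum <- function(model, max_sites = 6, blocked = TRUE) {
  stopifnot(inherits(model, "anderson_model"))
  n <- model$n_host + model$n_orb
  if (n > max_sites)
    stop(sprintf(paste0(
      "cluster has %d sites > cap of %d; ED is an oracle for small ",
      "fixtures - use the QMC solver (run_qmc) for larger clusters"),
      n, max_sites))
  h <- one_body_matrix(model)
  imp <- model$n_host + seq_len(model$n_orb)
  pop <- popcount_table(n)
  blocks <- list()
  if (blocked) {
    for (Nup in 0:n) for (Ndn in 0:n) {
      bu <- which(pop == Nup) - 1L
      bd <- which(pop == Ndn) - 1L
      H <- ed_block_hamiltonian(h, model, imp, bu, bd, n)
      es <- eigen(H, symmetric = TRUE)
      # combined state encoding: up | (dn << n), up index fastest
      states <- as.vector(outer(bu, bd * 2^n, `+`))
      blocks[[length(blocks) + 1L]] <-
        list(Nup = Nup, Ndn = Ndn, values = es$values,
             vectors = es$vectors, states = states)
    }
  } else {
    states <- 0:(4^n - 1)
    H <- ed_dense_hamiltonian(h, model, imp, n)
    es <- eigen(H, symmetric = TRUE)
    blocks[[1L]] <- list(Nup = NA, Ndn = NA, values = es$values,
                         vectors = es$vectors, states = states)
  }
  structure(list(blocks = blocks, n_sites = n, n_host = model$n_host,
                 n_orb = model$n_orb, model = model),
            class = "ed_spectrum")
}

popcount_table <- function(nbits) {
  s <- 0:(2^nbits - 1)
  cnt <- integer(length(s))
  for (b in 0:(nbits - 1)) cnt <- cnt + bitwAnd(bitwShiftR(s, b), 1L)
  cnt
}

# One-spin-sector hopping Hamiltonian over configurations `conf` (integer
# encodings of occupied-site subsets), including one-body diagonal and the
# parallel-spin interaction on the impurity (diagonal in this sector).
spin_sector_hamiltonian <- function(h, Udp, imp, conf, n) {
  m <- length(conf)
  pos <- integer(2^n); pos[conf + 1L] <- seq_len(m)
  H <- matrix(0, m, m)
  nmat <- occ_bits(conf, n)          # m x n occupations
  diag(H) <- drop(nmat %*% diag(h)) + Udp * pair_energy(nmat, imp)
  nz <- which(h != 0 & upper.tri(h), arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1]; j <- nz[k, 2]; t <- h[i, j]
    bi <- 2L^(i - 1L); bj <- 2L^(j - 1L)
    has_j <- bitwAnd(conf, bj) != 0L
    no_i <- bitwAnd(conf, bi) == 0L
    src <- which(has_j & no_i)
    if (!length(src)) next
    c0 <- conf[src]
    c1 <- c0 - bj + bi
    sgn <- jw_sign(c0, j) * jw_sign(c0 - bj, i)
    dst <- pos[c1 + 1L]
    for (q in seq_along(src)) {
      H[dst[q], src[q]] <- H[dst[q], src[q]] + t * sgn[q]
      H[src[q], dst[q]] <- H[src[q], dst[q]] + t * sgn[q]
    }
  }
  H
}

# Jordan-Wigner sign for acting with c_site / c_site^dagger on config:
# (-1)^(number of occupied sites below `site`).
jw_sign <- function(conf, site) {
  if (site == 1L) return(rep(1, length(conf)))
  mask <- 2L^(site - 1L) - 1L
  below <- bitwAnd(conf, mask)
  cnt <- integer(length(conf))
  for (b in 0:(site - 2L)) cnt <- cnt + bitwAnd(bitwShiftR(below, b), 1L)
  1 - 2 * (cnt %% 2)
}

occ_bits <- function(conf, n) {
  out <- matrix(0, length(conf), n)
  for (b in seq_len(n)) out[, b] <- bitwAnd(bitwShiftR(conf, b - 1L), 1L)
  out
}

pair_energy <- function(nmat, imp) {
  if (length(imp) < 2) return(numeric(nrow(nmat)))
  e <- numeric(nrow(nmat))
  for (a in 2:length(imp)) for (b in 1:(a - 1))
    e <- e + nmat[, imp[a]] * nmat[, imp[b]]
  e
}

ed_block_hamiltonian <- function(h, model, imp, bu, bd, n) {
  Hu <- spin_sector_hamiltonian(h, model$Udprime, imp, bu, n)
  Hd <- spin_sector_hamiltonian(h, model$Udprime, imp, bd, n)
  mu_ <- length(bu); md <- length(bd)
  H <- kronecker(diag(md), Hu) + kronecker(Hd, diag(mu_))
  # cross-spin diagonal: U n_up n_dn (intra) + U' opposite-spin inter
  nu <- occ_bits(bu, n)[, imp, drop = FALSE]
  nd <- occ_bits(bd, n)[, imp, drop = FALSE]
  no <- length(imp)
  cross <- matrix(0, mu_, md)
  for (v in seq_len(no)) cross <- cross + model$U * outer(nu[, v], nd[, v])
  if (no >= 2) for (a in 2:no) for (b in 1:(a - 1))
    cross <- cross + model$Uprime *
      (outer(nu[, a], nd[, b]) + outer(nu[, b], nd[, a]))
  diag(H) <- diag(H) + as.vector(cross)
  H
}

# Unblocked path: full 4^n Fock space, independent construction via
# Kronecker lifting of single-spin sectors over all particle numbers.
ed_dense_hamiltonian <- function(h, model, imp, n) {
  conf <- 0:(2^n - 1)
  Hu <- spin_sector_hamiltonian(h, model$Udprime, imp, conf, n)
  H <- kronecker(diag(2^n), Hu) + kronecker(Hu, diag(2^n))
  nu <- occ_bits(conf, n)[, imp, drop = FALSE]
  no <- length(imp)
  cross <- matrix(0, 2^n, 2^n)
  for (v in seq_len(no)) cross <- cross + model$U * outer(nu[, v], nu[, v])
  if (no >= 2) for (a in 2:no) for (b in 1:(a - 1))
    cross <- cross + model$Uprime *
      (outer(nu[, a], nu[, b]) + outer(nu[, b], nu[, a]))
  diag(H) <- diag(H) + as.vector(cross)
  H
}

#' All eigenvalues of an ED spectrum
#' @param spectrum an `ed_spectrum`
#' @return sorted numeric vector over all symmetry blocks
#' @export
ed_eigenvalues <- function(spectrum) {
  sort(unlist(lapply(spectrum$blocks, `[[`, "values")))
}

#' Thermal expectation value from an ED spectrum
#'
#' Evaluates Tr[exp(-beta H) O] / Z with overflow-safe shifting by the
#' ground-state energy. `observable` is either a numeric vector giving the
#' diagonal of O in the occupation basis, indexed by the integer state
#' encoding plus one (length 4^n_sites), or a function(state_ints) that
#' returns that diagonal.
#'
#' @param spectrum an `ed_spectrum`
#' @param T_kelvin temperature in K (or give `beta` in 1/eV)
#' @param observable diagonal of the observable in the occupation basis
#' @param beta inverse temperature, alternative to `T_kelvin`
#' @return the exact thermal expectation value
#' @export
ed_thermal_expectation <- function(spectrum, T_kelvin = NULL, observable,
                                   beta = NULL) {
  if (is.null(beta)) beta <- beta_from_T(T_kelvin)
  E0 <- min(vapply(spectrum$blocks, function(b) min(b$values), 0))
  Z <- 0; acc <- 0
  for (b in spectrum$blocks) {
    w <- exp(-beta * (b$values - E0))
    if (is.function(observable)) od <- observable(b$states)
    else od <- observable[b$states + 1L]
    # <k|O|k> for diagonal O: weights |v_bk|^2
    ok <- drop(crossprod(b$vectors^2, od))
    Z <- Z + sum(w)
    acc <- acc + sum(w * ok)
  }
  acc / Z
}

#' Grand potential from an ED spectrum
#' @param spectrum an `ed_spectrum`
#' @param T_kelvin temperature in K (or give `beta` in 1/eV)
#' @param beta inverse temperature, alternative to `T_kelvin`
#' @return Omega = -ln(Z)/beta in eV (energies already include -mu N)
#' @export
ed_grand_potential <- function(spectrum, T_kelvin = NULL, beta = NULL) {
  if (is.null(beta)) beta <- beta_from_T(T_kelvin)
  E0 <- min(vapply(spectrum$blocks, function(b) min(b$values), 0))
  Z <- sum(vapply(spectrum$blocks,
                  function(b) sum(exp(-beta * (b$values - E0))), 0))
  E0 - log(Z) / beta
}

# Diagonal of per-site occupations in the occupation basis.
state_occupations <- function(states, n_sites) {
  up <- occ_bits(bitwAnd(states, 2L^n_sites - 1L), n_sites)
  dn <- occ_bits(bitwShiftR(states, n_sites), n_sites)
  list(up = up, dn = dn)
}

#' Standard thermal observables from an ED spectrum
#'
#' Computes the observables the QMC solver also estimates: per-site
#' occupations, impurity double occupancies, the site-site z-moment
#' correlation matrix <m_a m_b> (m_a = n_a_up - n_a_dn in Bohr
#' magnetons), total moment statistics, the total electron number, and
#' the static susceptibility chi_t = beta (<M^2> - <M>^2) in muB^2/eV
#' (total S_z is conserved, so this equals the tau-integrated correlator).
#'
#' @param spectrum an `ed_spectrum`
#' @param T_kelvin temperature in K (or give `beta` in 1/eV)
#' @param beta inverse temperature, alternative to `T_kelvin`
#' @return list with `occ_up`, `occ_dn` (per site), `docc` (per impurity
#'   orbital), `mz_corr` (n_sites x n_sites), `M_tot`, `M2_tot`, `chi_t`,
#'   `N_total`
#' @export
ed_observables <- function(spectrum, T_kelvin = NULL, beta = NULL) {
  if (is.null(beta)) beta <- beta_from_T(T_kelvin)
  n <- spectrum$n_sites
  imp <- spectrum$n_host + seq_len(spectrum$n_orb)
  expectation <- function(fn)
    ed_thermal_expectation(spectrum, beta = beta, observable = fn)
  occf <- function(states) state_occupations(states, n)
  occ_up <- vapply(seq_len(n), function(a)
    expectation(function(s) occf(s)$up[, a]), 0)
  occ_dn <- vapply(seq_len(n), function(a)
    expectation(function(s) occf(s)$dn[, a]), 0)
  docc <- vapply(imp, function(a)
    expectation(function(s) { o <- occf(s); o$up[, a] * o$dn[, a] }), 0)
  mz_corr <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    val <- expectation(function(s) {
      o <- occf(s)
      (o$up[, a] - o$dn[, a]) * (o$up[, b] - o$dn[, b])
    })
    mz_corr[a, b] <- val; mz_corr[b, a] <- val
  }
  M_tot <- expectation(function(s) {
    o <- occf(s); rowSums(o$up) - rowSums(o$dn)
  })
  M2_tot <- sum(mz_corr)
  list(occ_up = occ_up, occ_dn = occ_dn, docc = docc,
       mz_corr = mz_corr, M_tot = M_tot, M2_tot = M2_tot,
       chi_t = beta * (M2_tot - M_tot^2),
       N_total = sum(occ_up) + sum(occ_dn))
}
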
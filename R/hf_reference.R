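#' Hirsch-Fye building blocks (reference path)
#'
#' Pure-R implementations of the discrete Hubbard-Stratonovich
#' construction: each density-density pair (a, b) with coupling W is
#' decoupled on every time slice by an Ising field s = +/-1 via
#' exp(-dtau W (n_a - 1/2)(n_b - 1/2)) ~ sum_s exp(lambda s (n_a - n_b)),
#' cosh(lambda) = exp(dtau W / 2). The one-body energies entering the bath
#' propagator are shifted accordingly (see `hartree_shift`). These
#' routines are the slow, transparent path used for validation; `run_qmc`
#' uses the compiled core.
#'
#' @name hirsch_fye_reference
NULL

# Bath propagator for the QMC: impurity energies carry the Hartree shift
# that converts W n_a n_b into W (n_a - 1/2)(n_b - 1/2).
qmc_bath <- function(model, grid) {
  model$impurity_energies <- hartree_shift(model)
  bath_g0(model, grid)
}

#' Initialize a Hubbard-Stratonovich field configuration
#' @param n_pairs number of interacting pairs
#' @param L number of time slices
#' @param random draw fields uniformly (default) or start all +1
#' @return integer matrix n_pairs x L with entries +/- 1
#' @export
hs_fields <- function(n_pairs, L, random = TRUE) {
  if (random) matrix(sample(c(-1L, 1L), n_pairs * L, replace = TRUE), n_pairs, L)
  else matrix(1L, n_pairs, L)
}

# Field potential V(s): per spin, diagonal over (orbital, slice) in
# orbital-major layout. Member a of a pair couples as +lambda s, member b
# as -lambda s.
field_potential <- function(fields, table, n_orb, L) {
  V <- list(matrix(0, n_orb, L), matrix(0, n_orb, L))
  for (p in seq_len(nrow(table))) {
    lam_s <- table$lambda[p] * fields[p, ]
    sa <- table$spin_a[p]; sb <- table$spin_b[p]
    V[[sa]][table$orb_a[p], ] <- V[[sa]][table$orb_a[p], ] + lam_s
    V[[sb]][table$orb_b[p], ] <- V[[sb]][table$orb_b[p], ] - lam_s
  }
  # flatten orbital-major: index (nu-1)*L + l
  lapply(V, function(m) as.vector(t(m)))
}

#' Interacting Green's function for fixed auxiliary fields (clean update)
#'
#' Solves the Dyson equation per spin channel, exact for the given field
#' configuration (no Monte Carlo error). In the sign convention used
#' throughout, g = -<T c c+>, it reads G = [1 + (1 + g0)(e^V - 1)]^{-1} g0
#' (the familiar (1 - g0) form holds in the opposite sign convention).
#' The configuration weight is the product over spins of det of the same
#' Dyson matrix.
#'
#' @param bath a `bath_g0` built with the QMC Hartree shift (see
#'   `run_qmc`); its `g0` is the (n_orb L) x (n_orb L) impurity block
#' @param fields integer matrix n_pairs x L of +/-1 fields
#' @param table a `pair_table`
#' @return list with per-spin matrices `up`, `dn`, the log |weight| and
#'   weight sign of the configuration
#' @export
green_from_fields <- function(bath, fields, table) {
  g0 <- bath$g0
  L <- bath$grid$L
  stopifnot(nrow(fields) == nrow(table), ncol(fields) == L)
  V <- field_potential(fields, table, bath$n_orb, L)
  out <- list()
  logw <- 0; sgn <- 1
  for (s in 1:2) {
    A <- diag(nrow(g0)) + (diag(nrow(g0)) + g0) %*% diag(expm1(V[[s]]))
    d <- determinant(A, logarithm = TRUE)
    logw <- logw + as.numeric(d$modulus)
    sgn <- sgn * as.numeric(d$sign)
    G <- solve(A, g0)
    out[[c("up", "dn")[s]]] <- G
    if (!all(is.finite(G)))
      stop("singular clean update: pathological lambda * L configuration")
  }
  out$log_weight <- logw
  out$sign <- sgn
  out
}

# Determinant ratio for flipping field (p, l), given current per-spin G.
# Returns the ratio R (may be negative) and the per-spin site/gamma lists
# needed to apply the update.
flip_ratio <- function(G, fields, table, p, l, L) {
  s_old <- fields[p, l]
  lam <- table$lambda[p]
  qa <- (table$orb_a[p] - 1L) * L + l
  qb <- (table$orb_b[p] - 1L) * L + l
  ga <- expm1(-2 * lam * s_old)   # member a: V_a = +lambda s
  gb <- expm1(+2 * lam * s_old)   # member b: V_b = -lambda s
  sa <- table$spin_a[p]; sb <- table$spin_b[p]
  if (sa != sb) {
    Ga <- if (sa == 1L) G$up else G$dn
    Gb <- if (sb == 1L) G$up else G$dn
    Ra <- 1 + ga * (1 + Ga[qa, qa])
    Rb <- 1 + gb * (1 + Gb[qb, qb])
    list(R = Ra * Rb,
         upd = list(list(spin = sa, q = qa, gamma = ga),
                    list(spin = sb, q = qb, gamma = gb)))
  } else {
    Gs <- if (sa == 1L) G$up else G$dn
    # 2x2 determinant: D_ij = delta_ij + (delta_ij + G_qi,qj) gamma_j
    D11 <- 1 + ga * (1 + Gs[qa, qa]); D12 <- gb * Gs[qa, qb]
    D21 <- ga * Gs[qb, qa];           D22 <- 1 + gb * (1 + Gs[qb, qb])
    list(R = D11 * D22 - D12 * D21,
         upd = list(list(spin = sa, q = qa, gamma = ga),
                    list(spin = sa, q = qb, gamma = gb)))
  }
}

# Rank-1 Sherman-Morrison update of one spin block for a single-site
# potential change gamma at site q.
rank1_update <- function(Gs, q, gamma) {
  Rq <- 1 + gamma * (1 + Gs[q, q])
  u <- Gs[, q]; u[q] <- u[q] + 1
  Gs - (gamma / Rq) * (u %o% Gs[q, ])
}

#' Propose a single Hubbard-Stratonovich field flip
#'
#' Computes the determinant ratio R for flipping field (p, l) and returns
#' it with a closure that applies the accepted flip to (G, fields) by
#' Sherman-Morrison updates. R can be negative; sign bookkeeping is the
#' caller's job (it is never clipped).
#'
#' @param G list with per-spin Green's matrices `up`, `dn`
#' @param fields current field matrix
#' @param table a `pair_table`
#' @param p pair index (row of `table`)
#' @param l time-slice index in 1..L
#' @param L number of time slices
#' @return list(R = ratio, apply = function() -> list(G, fields))
#' @export
propose_flip <- function(G, fields, table, p, l, L) {
  fr <- flip_ratio(G, fields, table, p, l, L)
  list(R = fr$R, apply = function() {
    for (u in fr$upd) {
      if (u$spin == 1L) G$up <- rank1_update(G$up, u$q, u$gamma)
      else G$dn <- rank1_update(G$dn, u$q, u$gamma)
    }
    fields[p, l] <- -fields[p, l]
    list(G = G, fields = fields)
  })
}

#' One reference sweep over all fields (pure R)
#'
#' Visits every (pair, slice) field once in sequential order, applying
#' heat-bath or Metropolis acceptance with Sherman-Morrison updates.
#' Used for validation; production sweeps run in the compiled core.
#'
#' @param G per-spin Green's matrices for the current fields
#' @param fields field matrix
#' @param table a `pair_table`
#' @param L slices
#' @param rule "heatbath" (default) or "metropolis"
#' @return list(G, fields, n_accept, n_prop, sign_flips)
#' @export
sweep_reference <- function(G, fields, table, L, rule = "heatbath") {
  n_acc <- 0L; n_prop <- 0L; sflip <- 0L
  for (p in seq_len(nrow(table))) for (l in seq_len(L)) {
    if (table$lambda[p] == 0) next
    pr <- propose_flip(G, fields, table, p, l, L)
    n_prop <- n_prop + 1L
    acc_p <- if (rule == "heatbath") abs(pr$R) / (1 + abs(pr$R))
             else min(1, abs(pr$R))
    if (stats::runif(1) < acc_p) {
      res <- pr$apply()
      G <- res$G; fields <- res$fields
      n_acc <- n_acc + 1L
      if (pr$R < 0) sflip <- sflip + 1L
    }
  }
  list(G = G, fields = fields, n_accept = n_acc, n_prop = n_prop,
       sign_flips = sflip)
}

#' Exhaustive enumeration of the discrete path integral
#'
#' Sums the Hirsch-Fye weight over all 2^(n_pairs L) field
#' configurations, evaluating observables by Wick's theorem per
#' configuration. Exact at fixed dtau (no Monte Carlo error); feasible
#' only for n_pairs * L up to ~16. The benchmark for both the QMC sampler
#' and, at small dtau, the ED oracle.
#'
#' @param model an `anderson_model`
#' @param grid a `tau_grid`
#' @return list with `occ_up`, `occ_dn`, `docc` (impurity), `sign_avg`,
#'   and `n_config`
#' @export
enumerate_hf <- function(model, grid) {
  table <- pair_table(model, grid)
  bath <- qmc_bath(model, grid)
  L <- grid$L; np <- nrow(table); no <- model$n_orb
  if (np * L > 16) stop("enumeration limited to n_pairs * L <= 16")
  nconf <- 2^(np * L)
  Zs <- 0; Za <- 0
  occ_up <- numeric(no); occ_dn <- numeric(no); docc <- numeric(no)
  logw_all <- numeric(nconf)
  cache <- vector("list", nconf)
  for (k in seq_len(nconf)) {
    bits <- bitwAnd(bitwShiftR(k - 1L, 0:(np * L - 1L)), 1L)
    fields <- matrix(2L * bits - 1L, np, L)
    cache[[k]] <- green_from_fields(bath, fields, table)
    logw_all[k] <- cache[[k]]$log_weight
  }
  lw0 <- max(logw_all)
  for (k in seq_len(nconf)) {
    gg <- cache[[k]]
    w <- gg$sign * exp(logw_all[k] - lw0)
    diag_idx <- function(v) (v - 1L) * L + seq_len(L)
    nu <- vapply(seq_len(no), function(v) mean(1 + diag(gg$up)[diag_idx(v)]), 0)
    nd <- vapply(seq_len(no), function(v) mean(1 + diag(gg$dn)[diag_idx(v)]), 0)
    Zs <- Zs + w
    Za <- Za + abs(w)
    occ_up <- occ_up + w * nu
    occ_dn <- occ_dn + w * nd
    docc <- docc + w * vapply(seq_len(no), function(v) {
      mean((1 + diag(gg$up)[diag_idx(v)]) * (1 + diag(gg$dn)[diag_idx(v)]))
    }, 0)
  }
  list(occ_up = occ_up / Zs, occ_dn = occ_dn / Zs, docc = docc / Zs,
       sign_avg = Zs / Za, n_config = nconf)
}
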
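#' Effective magnetic moment from a static susceptibility
#'
#' Curie-law convention: M_eff = sqrt(3 k_B T chi). For a free spin S
#' (with g = 2) this returns g sqrt(S(S+1)) muB, so S = 2 maps to
#' 4.9 muB and S = 1/2 to sqrt(3) muB.
#'
#' @param chi static spin susceptibility in muB^2/eV (>= 0)
#' @param T_kelvin temperature in K
#' @return effective moment in muB
#' @export
effective_moment <- function(chi, T_kelvin) {
  if (any(chi < 0)) stop("negative susceptibility")
  sqrt(3 * k_B * T_kelvin * chi)
}

#' Instantaneous moment convention
#'
#' The alternative sqrt(3 <M_z^2>) estimate from the equal-time moment
#' fluctuation (isotropy factor 3 for the z component); reported
#' alongside the Curie-law convention because figure-style moment maps
#' can be defined either way.
#'
#' @param m2 equal-time <M_z^2> in muB^2
#' @return moment in muB
#' @export
instantaneous_moment <- function(m2) {
  if (any(m2 < 0)) stop("negative moment fluctuation")
  sqrt(3 * m2)
}

#' Susceptibility curve container
#'
#' @param T_kelvin temperatures (K, strictly positive)
#' @param chi susceptibilities (muB^2/eV)
#' @param err optional standard errors
#' @param provenance optional free-form list (model hash, solver settings)
#' @return data frame of class `susceptibility_curve`, sorted by T
#' @export
susceptibility_curve <- function(T_kelvin, chi, err = NA_real_,
                                 provenance = NULL) {
  stopifnot(all(T_kelvin > 0), length(T_kelvin) == length(chi))
  o <- order(T_kelvin)
  out <- data.frame(T_kelvin = T_kelvin[o], chi = chi[o],
                    err = rep_len(err, length(chi))[o])
  attr(out, "provenance") <- provenance
  class(out) <- c("susceptibility_curve", "data.frame")
  out
}

#' Curie-law fit of a susceptibility curve
#'
#' Weighted least squares of chi = C / T; the Curie constant fixes the
#' effective moment M_eff = sqrt(3 k_B C). When the data contain a
#' crossover between two Curie regimes (as oxy-heme does around
#' T* ~ 300 K) the single-regime fit is poor; with `piecewise = TRUE`
#' every interior split point is tried, the best split (minimum total
#' residual) is selected, and separate moments are reported for the low-
#' and high-T branches.
#'
#' @param curve a `susceptibility_curve` (or data frame with columns
#'   `T_kelvin`, `chi`, optionally `err`)
#' @param piecewise also fit a two-regime model (needs >= 6 points)
#' @return list with `C`, `M_eff`, `goodness` (reduced chi-square when
#'   errors are supplied, otherwise relative rms residual), and when
#'   piecewise: `T_star`, `M_eff_low`, `M_eff_high`, `crossover`
#'   (TRUE when the two-regime fit is decisively better)
#' @export
curie_fit <- function(curve, piecewise = FALSE) {
  stopifnot(nrow(curve) >= 3)
  T_ <- curve$T_kelvin; chi <- curve$chi
  err <- if ("err" %in% names(curve) && all(is.finite(curve$err)) &&
             all(curve$err > 0)) curve$err else NULL
  fit1 <- fit_curie_branch(T_, chi, err)
  out <- list(C = fit1$C, M_eff = sqrt(3 * k_B * fit1$C),
              goodness = fit1$goodness)
  if (piecewise && length(T_) >= 6) {
    best <- NULL
    for (k in 3:(length(T_) - 3)) {
      lo <- fit_curie_branch(T_[1:k], chi[1:k], err[1:k])
      hi <- fit_curie_branch(T_[(k + 1):length(T_)], chi[(k + 1):length(T_)],
                             err[(k + 1):length(T_)])
      tot <- lo$rss + hi$rss
      if (is.null(best) || tot < best$tot)
        best <- list(k = k, lo = lo, hi = hi, tot = tot)
    }
    out$T_star <- mean(T_[best$k + 0:1])
    out$M_eff_low <- sqrt(3 * k_B * max(0, best$lo$C))
    out$M_eff_high <- sqrt(3 * k_B * max(0, best$hi$C))
    out$goodness_piecewise <- best$tot / max(1, length(T_) - 2)
    # decisively better: two regimes explain the data much better than one
    out$crossover <- best$tot < 0.25 * fit1$rss
  }
  out
}

fit_curie_branch <- function(T_, chi, err = NULL) {
  x <- 1 / T_
  w <- if (is.null(err)) rep(1, length(T_)) else 1 / err^2
  C <- sum(w * x * chi) / sum(w * x^2)
  rss <- sum(w * (chi - C * x)^2)
  goodness <- if (is.null(err)) {
    sqrt(rss / length(T_)) / max(abs(chi))
  } else rss / max(1, length(T_) - 1)
  list(C = C, rss = rss, goodness = goodness)
}

#' Tune the chemical potential to a target electron number
#'
#' Adjusts mu so that the cluster holds `n_target` electrons (the
#' grand-canonical analogue of fixing the filling). The bracket is found
#' by expansion around the starting mu and then bisected; <N>(mu) is
#' monotone nondecreasing, and bisection is robust to the statistical
#' noise of a QMC-evaluated <N>.
#'
#' @param model an `anderson_model` with `n_target` set (or pass
#'   `n_target`)
#' @param T_kelvin temperature in K
#' @param solver "noninteracting" (fast; exact for U = 0), "ed" (exact,
#'   small clusters), or "qmc"
#' @param tol convergence tolerance on |<N> - n_target| (electrons)
#' @param n_target overrides `model$n_target`
#' @param max_expand bracket search limit in eV around the starting mu
#' @param qmc_args list of arguments passed on to `run_qmc`
#' @return list with `mu`, `N`, `n_eval`, and the tuned model in `model`
#' @export
tune_mu <- function(model, T_kelvin,
                    solver = c("noninteracting", "ed", "qmc"),
                    tol = 0.01, n_target = NULL, max_expand = 20,
                    qmc_args = list()) {
  solver <- match.arg(solver)
  if (is.null(n_target)) n_target <- model$n_target
  if (is.null(n_target)) stop("no target electron number given")
  beta <- beta_from_T(T_kelvin)
  n_eval <- 0L
  Nof <- function(mu) {
    n_eval <<- n_eval + 1L
    mm <- set_mu(model, mu)
    switch(solver,
      noninteracting = noninteracting_density(mm, beta = beta)$N_total,
      ed = ed_observables(ed_spectrum(mm), beta = beta)$N_total,
      qmc = {
        grid <- qmc_args$grid
        if (is.null(grid)) grid <- tau_grid(beta = beta, dtau = 0.25)
        args <- qmc_args[setdiff(names(qmc_args), "grid")]
        r <- do.call(run_qmc, c(list(model = mm, grid = grid,
                                     measure_hosts = TRUE), args))
        sum(r$occ_site_up + r$occ_site_dn)
      })
  }
  lo <- model$mu; hi <- model$mu
  Nlo <- Nof(lo); Nhi <- Nlo
  step <- 0.25
  while (Nlo > n_target && model$mu - lo < max_expand) {
    lo <- lo - step; Nlo <- Nof(lo); step <- step * 2
  }
  step <- 0.25
  while (Nhi < n_target && hi - model$mu < max_expand) {
    hi <- hi + step; Nhi <- Nof(hi); step <- step * 2
  }
  if (Nlo > n_target || Nhi < n_target)
    stop(sprintf("no bracket for N = %g within +-%g eV", n_target, max_expand))
  for (it in seq_len(100)) {
    mid <- (lo + hi) / 2
    Nm <- Nof(mid)
    if (abs(Nm - n_target) <= tol || (hi - lo) < 1e-10) break
    if (Nm < n_target) lo <- mid else hi <- mid
  }
  list(mu = mid, N = Nm, n_eval = n_eval, model = set_mu(model, mid))
}

#' Total-moment scan versus chemical potential
#'
#' Evaluates M_t(mu) = sqrt(3 k_B T chi_t(mu)) on a grid of chemical
#' potentials. With the interacting solvers this traces the suppression
#' of magnetism near the Fermi level that characterizes the oxy-like
#' electronic structure; the noninteracting solver gives the exact
#' free-fermion benchmark (chi = beta sum_k 2 f_k (1 - f_k)).
#'
#' @param model an `anderson_model`
#' @param T_kelvin temperature in K
#' @param mu_grid chemical potentials to scan (eV)
#' @param solver "noninteracting", "ed", or "qmc"
#' @param qmc_args list of arguments passed to `run_qmc` (include `grid`
#'   to override the default dtau = 0.25 discretization)
#' @return data frame with columns `mu`, `chi`, `M_t`, `err` (moment
#'   error, NA for exact solvers)
#' @export
moment_vs_mu_scan <- function(model, T_kelvin, mu_grid,
                              solver = c("noninteracting", "ed", "qmc"),
                              qmc_args = list()) {
  solver <- match.arg(solver)
  beta <- beta_from_T(T_kelvin)
  rows <- lapply(mu_grid, function(mu) {
    mm <- set_mu(model, mu)
    if (solver == "noninteracting") {
      es <- eigen(one_body_matrix(mm), symmetric = TRUE, only.values = TRUE)
      f <- fermi_fn(es$values, beta)
      chi <- beta * sum(2 * f * (1 - f))
      err <- NA_real_
    } else if (solver == "ed") {
      chi <- ed_observables(ed_spectrum(mm), beta = beta)$chi_t
      err <- NA_real_
    } else {
      grid <- qmc_args$grid
      if (is.null(grid)) grid <- tau_grid(beta = beta, dtau = 0.25)
      args <- qmc_args[setdiff(names(qmc_args), "grid")]
      r <- do.call(run_qmc, c(list(model = mm, grid = grid), args))
      chi <- max(0, r$chi_t)
      err <- r$chi_t_err
    }
    M <- effective_moment(chi, T_kelvin)
    merr <- if (is.na(err)) NA_real_ else {
      if (chi > 0) 0.5 * M * err / chi else sqrt(3 * k_B * T_kelvin * err)
    }
    data.frame(mu = mu, chi = chi, M_t = M, err = merr)
  })
  do.call(rbind, rows)
}

#' Project the QMC moment distribution onto atomic sites
#'
#' Builds a per-atom signed moment map in the style of a magnetic-moment
#' density plot: the moment assigned to atom A is
#' sum_states w(A, state) <M_z,state M_z,t> / sqrt(<M_z,t^2>),
#' i.e. each cluster state's correlation with the total moment,
#' distributed over atoms by the projection weights. Host states project
#' onto porphyrin/ligand atoms; impurity (Fe 3d) states project onto the
#' Fe site. Sites that correlate antiferromagnetically with the dominant
#' moment come out negative. The atomic moments sum to the instantaneous
#' total moment sqrt(<M_z,t^2>) exactly (bookkeeping identity).
#'
#' @param result a `qmc_result` with host measurements
#' @param projection matrix of weights, rows = cluster states in solver
#'   order (host states then impurity orbitals), columns = atoms; every
#'   row must sum to 1
#' @param atoms optional atom labels (defaults to projection colnames)
#' @return data frame of class `moment_density_map` with columns `atom`,
#'   `moment`; attribute `total` holds sqrt(<M_z,t^2>)
#' @export
project_moment_density <- function(result, projection, atoms = NULL) {
  stopifnot(inherits(result, "qmc_result"))
  if (is.null(result$state_total_corr))
    stop("result lacks host measurements (run_qmc with measure_hosts = TRUE)")
  projection <- as.matrix(projection)
  n_state <- length(result$state_total_corr)
  if (nrow(projection) != n_state)
    stop(sprintf("projection must have %d rows (host states then impurity orbitals)",
                 n_state))
  if (max(abs(rowSums(projection) - 1)) > 1e-8)
    stop("projection rows must each sum to 1")
  m2 <- result$M2_tot
  if (m2 <= 0) stop("total moment fluctuation is not positive")
  contrib <- result$state_total_corr / sqrt(m2)
  moments <- drop(crossprod(projection, contrib))
  if (is.null(atoms)) atoms <- colnames(projection)
  if (is.null(atoms)) atoms <- paste0("atom", seq_along(moments))
  out <- data.frame(atom = atoms, moment = moments)
  attr(out, "total") <- sqrt(m2)
  class(out) <- c("moment_density_map", "data.frame")
  out
}

#' Fe-host moment correlations
#'
#' Per-host-state equal-time correlation <M_z,Fe M_z,m> between the total
#' impurity (Fe 3d) moment and each host state's moment, in muB^2.
#' Negative values signal antiferromagnetic Fe-host correlations.
#'
#' @param result a `qmc_result` with host measurements
#' @return data frame with columns `host_state`, `energy` (eV), `corr`,
#'   `err`, and `label` when the model carries host labels
#' @export
fe_host_correlation <- function(result) {
  stopifnot(inherits(result, "qmc_result"))
  if (is.null(result$fe_host_corr))
    stop("result lacks host measurements (run_qmc with measure_hosts = TRUE)")
  nh <- result$model$n_host
  imp <- nh + seq_len(result$model$n_orb)
  err <- sqrt(colSums(result$mz_corr_err[imp, seq_len(nh), drop = FALSE]^2))
  out <- data.frame(host_state = seq_len(nh),
                    energy = result$model$host_energies,
                    corr = result$fe_host_corr,
                    err = err)
  if (!is.null(result$model$host_labels)) out$label <- result$model$host_labels
  out
}
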
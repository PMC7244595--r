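#' Hirsch-Fye quantum Monte Carlo solver
#'
#' Samples the discrete Hubbard-Stratonovich field configurations of an
#' Anderson impurity model by single-field flips with determinant-ratio
#' acceptance and Sherman-Morrison fast updates (compiled core), and
#' accumulates binned, sign-reweighted estimators with jackknife errors.
#'
#' Host observables are never sampled directly: because the interactions
#' live on the impurity only, the full-cluster Green's function follows
#' from the impurity one through the exact embedding relation
#' G_full = g + g[, imp] g_imp^-1 (G_imp - g_imp) g_imp^-1 g[imp, ], so
#' the QMC matrices stay of size (n_orb L) regardless of the number of
#' host states. That is what makes keeping every host level tractable.
#'
#' @param model an `anderson_model`
#' @param grid a `tau_grid`
#' @param n_warmup warmup sweeps before measuring
#' @param n_sweeps measured sweeps
#' @param n_bins number of bins for jackknife errors (>= 4, default 16)
#' @param seed integer seed (set for reproducibility; same seed gives a
#'   bit-identical result)
#' @param measure_interval sweeps between measurements
#' @param clean_interval sweeps between from-scratch Green rebuilds; the
#'   fast-update drift is checked at each rebuild
#' @param rule "heatbath" (default) or "metropolis" acceptance
#' @param shuffle visit fields in a random order instead of sequentially
#' @param measure_hosts reconstruct host observables via the embedding
#'   relation (total moment, susceptibility, Fe-host correlations)
#' @param measure_tau accumulate the imaginary-time-displaced total-moment
#'   correlator (cross-check of the equal-time susceptibility; intended
#'   for small clusters)
#' @param spin_exchange interleave the exact global spin-exchange move
#'   (negate intra-orbital fields, exchange the fields of spin-mirrored
#'   pairs, swap the spin blocks): an always-accepted, weight-preserving
#'   involution that decorrelates the orientation of long-lived local
#'   moments and symmetrizes the spin-resolved estimators (default TRUE)
#' @param drift_tol warn and rebuild when the fast-update drift exceeds
#'   this (default 1e-6)
#' @return object of class `qmc_result`; see Details
#' @details The result carries per-spin-orbital occupations, impurity
#'   pair densities and double occupancies, the site-site z-moment
#'   correlation matrix, total-moment statistics and the static
#'   susceptibility chi_t = beta <M^2> in muB^2/eV (the zero-field
#'   estimator; <M> = 0 by symmetry and total S_z is conserved), per-host
#'   Fe-host moment correlations, the average fermionic sign, acceptance
#'   rate, maximum fast-update drift, and all solver settings. Estimators
#'   are <O sgn>/<sgn> with jackknife errors over bins; results with
#'   |<sgn>| < 0.05 are flagged unreliable.
#' @export
run_qmc <- function(model, grid, n_warmup = 200, n_sweeps = 2000,
                    n_bins = 16, seed = NULL, measure_interval = 5,
                    clean_interval = 50,
                    rule = c("heatbath", "metropolis"), shuffle = FALSE,
                    measure_hosts = TRUE, measure_tau = FALSE,
                    spin_exchange = TRUE, drift_tol = 1e-6) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "anderson_model"), inherits(grid, "tau_grid"))
  if (n_bins < 4) stop("n_bins must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  table <- pair_table(model, grid)
  bath <- qmc_bath(model, grid)
  L <- grid$L; no <- model$n_orb; nh <- model$n_host
  n_site <- nh + no
  g0 <- bath$g0
  g0inv <- solve(g0)
  emb <- if (measure_hosts || measure_tau)
    embedding_pieces(bath$eig, grid, nh, no, displaced = measure_tau)
  else NULL
  pairs_cpp <- cbind(table$orb_a - 1L, table$spin_a - 1L,
                     table$orb_b - 1L, table$spin_b - 1L)
  storage.mode(pairs_cpp) <- "integer"

  fields <- hs_fields(nrow(table), L)
  st <- clean_state(g0, fields, table, no, L)
  drift_max <- 0
  # spin-mirror permutation: intra pairs map to themselves with negated
  # field, inter pairs exchange fields with their spin-flipped partner
  partner <- integer(nrow(table)); psign <- integer(nrow(table))
  for (p in seq_len(nrow(table))) {
    if (table$orb_a[p] == table$orb_b[p]) { partner[p] <- p; psign[p] <- -1L }
    else {
      q <- which(table$orb_a == table$orb_a[p] & table$orb_b == table$orb_b[p] &
                 table$spin_a == 3L - table$spin_a[p] &
                 table$spin_b == 3L - table$spin_b[p])
      partner[p] <- q; psign[p] <- 1L
    }
  }
  exchange_spins <- function(state) {
    state$fields <- state$fields[partner, , drop = FALSE] * psign
    tmp <- state$Gup; state$Gup <- state$Gdn; state$Gdn <- tmp
    state
  }

  advance <- function(state, nsw) {
    done <- 0
    while (done < nsw) {
      k <- min(clean_interval, nsw - done)
      out <- hf_sweeps_cpp(state$Gup, state$Gdn, state$fields, pairs_cpp,
                           table$lambda, L, k, rule == "heatbath",
                           shuffle, state$sign)
      state$Gup <- out$Gup; state$Gdn <- out$Gdn
      state$fields <- out$fields; state$sign <- out$sign
      state$n_acc <- state$n_acc + out$n_accept
      state$n_prop <- state$n_prop + out$n_prop
      done <- done + k
      state$since_clean <- state$since_clean + k
      if (state$since_clean >= clean_interval) {
        cl <- clean_state(g0, state$fields, table, no, L)
        drift <- max(abs(state$Gup - cl$Gup), abs(state$Gdn - cl$Gdn))
        drift_max <<- max(drift_max, drift)
        if (drift > drift_tol)
          warning(sprintf("fast-update drift %.2e exceeded %.1e; rebuilt",
                          drift, drift_tol))
        state$Gup <- cl$Gup; state$Gdn <- cl$Gdn; state$sign <- cl$sign
        state$since_clean <- 0
      }
    }
    state
  }

  st$n_acc <- 0; st$n_prop <- 0; st$since_clean <- 0
  st <- advance(st, n_warmup)
  st$n_acc <- 0; st$n_prop <- 0

  n_meas <- max(n_bins, floor(n_sweeps / measure_interval))
  meas_per_bin <- max(1L, floor(n_meas / n_bins))
  n_meas <- meas_per_bin * n_bins
  bins <- NULL
  for (b in seq_len(n_bins)) {
    acc <- NULL
    sgn_sum <- 0
    for (im in seq_len(meas_per_bin)) {
      st <- advance(st, measure_interval)
      if (spin_exchange) st <- exchange_spins(st)
      mm <- measure_config(st$Gup, st$Gdn, g0, g0inv, table, no, nh, L,
                           grid, emb, measure_hosts, measure_tau)
      v <- unlist(mm) * st$sign
      acc <- if (is.null(acc)) v else acc + v
      sgn_sum <- sgn_sum + st$sign
    }
    bins <- rbind(bins, c(acc, .sgn = sgn_sum))
  }
  finalize_qmc(bins, n_bins, meas_per_bin, model, grid, table,
               st, drift_max, n_meas,
               settings = list(n_warmup = n_warmup, n_sweeps = n_sweeps,
                               n_bins = n_bins, seed = seed,
                               measure_interval = measure_interval,
                               clean_interval = clean_interval,
                               rule = rule, shuffle = shuffle,
                               dtau = grid$dtau, L = L, beta = grid$beta),
               measure_hosts, measure_tau)
}

clean_state <- function(g0, fields, table, no, L) {
  V <- field_potential(fields, table, no, L)
  cu <- hf_clean_cpp(g0, V[[1]])
  cd <- hf_clean_cpp(g0, V[[2]])
  list(Gup = cu$G, Gdn = cd$G, fields = fields,
       sign = as.integer(cu$sign * cd$sign))
}

# Precomputed propagator slabs for reconstructing host observables:
# geq   : equal-time full-cluster propagator (n_site x n_site, 0+),
# B[, , l]: g[(all sites, slice l), (imp orbitals, all slices)],
# Cc[, , l]: g[(imp orbitals, all slices), (all sites, slice l)],
# and for the displaced correlator the slabs g(tau_l) over all sites.
embedding_pieces <- function(es, grid, nh, no, displaced = FALSE) {
  L <- grid$L; dtau <- grid$dtau; beta <- grid$beta
  n_site <- nh + no
  imp <- nh + seq_len(no)
  all_s <- seq_len(n_site)
  gd_ai <- array(0, c(n_site, no, 2 * L - 1))  # g_{site, imp}(d dtau)
  gd_ia <- array(0, c(no, n_site, 2 * L - 1))
  for (d in -(L - 1):(L - 1)) {
    gd_ai[, , d + L] <- g_tau_sites(es, beta, d * dtau, all_s, imp)
    gd_ia[, , d + L] <- g_tau_sites(es, beta, d * dtau, imp, all_s)
  }
  B <- array(0, c(n_site, no * L, L))
  Cc <- array(0, c(no * L, n_site, L))
  for (l in seq_len(L)) for (v in seq_len(no)) {
    # B: rows = sites at slice l, cols = (imp nu, slice j): g_{a,nu}((l-j) dtau)
    B[, (v - 1) * L + seq_len(L), l] <-
      matrix(gd_ai[, v, (l - seq_len(L)) + L], nrow = n_site)
    # Cc: rows = (imp nu, slice j), cols = sites at slice l: g_{nu,a}((j-l) dtau)
    Cc[(v - 1) * L + seq_len(L), , l] <-
      t(matrix(gd_ia[v, , (seq_len(L) - l) + L], nrow = n_site))
  }
  geq <- g_tau_sites(es, beta, 0, all_s, all_s)
  out <- list(B = B, Cc = Cc, geq = geq, n_site = n_site, imp = imp)
  if (displaced) {
    gtau <- array(0, c(n_site, n_site, L))
    for (l in seq_len(L))
      gtau[, , l] <- g_tau_sites(es, beta, (l - 1) * dtau, all_s, all_s)
    gtau_m <- array(0, c(n_site, n_site, L))
    for (l in seq_len(L))
      gtau_m[, , l] <- g_tau_sites(es, beta, -(l - 1) * dtau, all_s, all_s)
    out$gtau <- gtau; out$gtau_m <- gtau_m
  }
  out
}

# Per-configuration Wick measurements. Returns a flat named list so the
# binning code can accumulate sums generically.
measure_config <- function(Gup, Gdn, g0, g0inv, table, no, nh, L, grid,
                           emb, measure_hosts, measure_tau) {
  didx <- function(v) (v - 1L) * L + seq_len(L)
  dup <- diag(Gup); ddn <- diag(Gdn)
  nup <- vapply(seq_len(no), function(v) 1 + dup[didx(v)], numeric(L))
  ndn <- vapply(seq_len(no), function(v) 1 + ddn[didx(v)], numeric(L))
  nup <- matrix(nup, L, no); ndn <- matrix(ndn, L, no)
  out <- list(occ_up = colMeans(nup), occ_dn = colMeans(ndn),
              # spin-symmetrized occupation: equals both spin channels at
              # zero field and carries far less moment-orientation noise
              nocc = colMeans(nup + ndn) / 2)
  # pair densities <n_a n_b> per interaction pair (slice-averaged)
  pd <- numeric(nrow(table))
  for (p in seq_len(nrow(table))) {
    oa <- table$orb_a[p]; ob <- table$orb_b[p]
    na_ <- if (table$spin_a[p] == 1L) nup[, oa] else ndn[, oa]
    nb_ <- if (table$spin_b[p] == 1L) nup[, ob] else ndn[, ob]
    if (table$spin_a[p] != table$spin_b[p]) {
      pd[p] <- mean(na_ * nb_)
    } else {
      Gs <- if (table$spin_a[p] == 1L) Gup else Gdn
      ia <- didx(oa); ib <- didx(ob)
      gab <- Gs[cbind(ia, ib)]; gba <- Gs[cbind(ib, ia)]
      pd[p] <- mean(na_ * nb_ - gab * gba)
    }
  }
  out$pair_dens <- pd
  if (measure_hosts || measure_tau) {
    n_site <- emb$n_site
    Xu <- g0inv %*% (Gup - g0) %*% g0inv
    Xd <- g0inv %*% (Gdn - g0) %*% g0inv
    Cfull <- matrix(0, n_site, n_site)
    nupf <- numeric(n_site); ndnf <- numeric(n_site)
    m_l <- matrix(0, n_site, L)   # per-slice moment profile
    for (l in seq_len(L)) {
      Bu <- emb$B[, , l]; Cv <- emb$Cc[, , l]
      Gfu <- emb$geq + Bu %*% Xu %*% Cv
      Gfd <- emb$geq + Bu %*% Xd %*% Cv
      nu <- 1 + diag(Gfu); nd <- 1 + diag(Gfd)
      m_l[, l] <- nu - nd
      Cl <- outer(nu - nd, nu - nd) - Gfu * t(Gfu) - Gfd * t(Gfd)
      diag(Cl) <- nu + nd - 2 * nu * nd
      Cfull <- Cfull + Cl
      nupf <- nupf + nu; ndnf <- ndnf + nd
    }
    Cfull <- Cfull / L; nupf <- nupf / L; ndnf <- ndnf / L
    out$occ_site_up <- nupf
    out$occ_site_dn <- ndnf
    out$mz_corr <- as.vector(Cfull)
    out$M_tot <- sum(nupf - ndnf)
    out$M2_tot <- sum(Cfull)
    if (measure_tau) {
      # <M(tau_l) M(0)>: time-displaced full-cluster blocks via embedding
      tc <- numeric(L)
      tc[1] <- sum(Cfull)  # equal-time value (0+ convention)
      m0 <- m_l[, 1]
      for (l in seq_len(L)[-1]) {
        Gl0u <- emb$gtau[, , l] + emb$B[, , l] %*% Xu %*% emb$Cc[, , 1]
        Gl0d <- emb$gtau[, , l] + emb$B[, , l] %*% Xd %*% emb$Cc[, , 1]
        G0lu <- emb$gtau_m[, , l] + emb$B[, , 1] %*% Xu %*% emb$Cc[, , l]
        G0ld <- emb$gtau_m[, , l] + emb$B[, , 1] %*% Xd %*% emb$Cc[, , l]
        tc[l] <- sum(outer(m_l[, l], m0)) -
          sum(t(G0lu) * Gl0u) - sum(t(G0ld) * Gl0d)
      }
      out$tau_corr <- tc
    }
  }
  out
}

finalize_qmc <- function(bins, n_bins, meas_per_bin, model, grid, table,
                         st, drift_max, n_meas, settings,
                         measure_hosts, measure_tau) {
  L <- grid$L; no <- model$n_orb; nh <- model$n_host
  n_site <- nh + no
  sgn_col <- ncol(bins)
  obs_names <- colnames(bins)[-sgn_col]
  tot_sgn <- sum(bins[, sgn_col])
  tot_obs <- colSums(bins[, -sgn_col, drop = FALSE])
  est <- tot_obs / tot_sgn
  # jackknife leave-one-bin-out for every accumulated component
  jk <- matrix(0, n_bins, length(est))
  for (b in seq_len(n_bins))
    jk[b, ] <- (tot_obs - bins[b, -sgn_col]) / (tot_sgn - bins[b, sgn_col])
  jk_mean <- colMeans(jk)
  err <- sqrt(pmax(0, (n_bins - 1) / n_bins *
                     colSums(sweep(jk, 2, jk_mean)^2)))
  names(est) <- names(err) <- obs_names
  pick <- function(prefix) {
    sel <- startsWith(obs_names, prefix)
    list(value = unname(est[sel]), err = unname(err[sel]), jk = jk[, sel, drop = FALSE])
  }
  occ_up <- pick("occ_up"); occ_dn <- pick("occ_dn"); occ_s <- pick("nocc")
  pair_dens <- pick("pair_dens")
  intra <- which(table$spin_a != table$spin_b & table$orb_a == table$orb_b)
  res <- list(
    model = model, grid = grid, table = table,
    occ_up = occ_up$value[seq_len(no)], occ_up_err = occ_up$err[seq_len(no)],
    occ_dn = occ_dn$value[seq_len(no)], occ_dn_err = occ_dn$err[seq_len(no)],
    occ = occ_s$value[seq_len(no)], occ_err = occ_s$err[seq_len(no)],
    pair_dens = pair_dens$value, pair_dens_err = pair_dens$err,
    docc = pair_dens$value[intra], docc_err = pair_dens$err[intra],
    sign_avg = tot_sgn / n_meas,
    acceptance = st$n_acc / max(1, st$n_prop),
    drift_max = drift_max,
    n_meas = n_meas, settings = settings)
  sj <- bins[, sgn_col]
  res$sign_err <- stats::sd(sj / meas_per_bin) / sqrt(n_bins)
  if (measure_hosts) {
    mz <- pick("mz_corr")
    Cm <- matrix(mz$value, n_site, n_site)
    res$mz_corr <- Cm
    res$mz_corr_err <- matrix(mz$err, n_site, n_site)
    res$occ_site_up <- pick("occ_site_up")$value
    res$occ_site_dn <- pick("occ_site_dn")$value
    M1 <- pick("M_tot"); M2 <- pick("M2_tot")
    res$M_tot <- M1$value; res$M_tot_err <- M1$err
    res$M2_tot <- M2$value; res$M2_tot_err <- M2$err
    # zero-field estimator: <M> = 0 exactly by symmetry, so chi_t is
    # beta <M^2> (subtracting the sampled mean^2 would only inject the
    # long autocorrelation of the total-moment orientation)
    res$chi_t <- grid$beta * M2$value
    res$chi_t_err <- grid$beta * M2$err
    imp <- nh + seq_len(no)
    res$fe_host_corr <- if (nh > 0)
      colSums(Cm[imp, seq_len(nh), drop = FALSE]) else numeric(0)
    res$state_total_corr <- rowSums(Cm)
    res$M2_fe <- sum(Cm[imp, imp])
  }
  if (measure_tau) {
    tc <- pick("tau_corr")
    res$tau_corr <- tc$value
    res$tau_corr_err <- tc$err
    res$chi_tau <- grid$dtau * sum(tc$value)
  }
  if (abs(res$sign_avg) < 0.05) {
    res$unreliable <- TRUE
    warning("average sign below 0.05: estimators unreliable")
  } else res$unreliable <- FALSE
  class(res) <- "qmc_result"
  res
}

#' @export
print.qmc_result <- function(x, ...) {
  cat(sprintf("Hirsch-Fye QMC result: %d orbital(s), %d host state(s), beta = %g, L = %d\n",
              x$model$n_orb, x$model$n_host, x$grid$beta, x$grid$L))
  cat(sprintf("  sweeps %d (bins %d), acceptance %.2f, <sign> = %.3f +- %.3f\n",
              x$settings$n_sweeps, x$settings$n_bins, x$acceptance,
              x$sign_avg, x$sign_err))
  for (v in seq_along(x$occ_up))
    cat(sprintf("  orbital %d: <n_up> = %.4f(%.0f) <n_dn> = %.4f(%.0f) <n_up n_dn> = %.4f(%.0f)\n",
                v, x$occ_up[v], 1e4 * x$occ_up_err[v],
                x$occ_dn[v], 1e4 * x$occ_dn_err[v],
                x$docc[v], 1e4 * x$docc_err[v]))
  if (!is.null(x$chi_t))
    cat(sprintf("  chi_t = %.4f +- %.4f muB^2/eV, <M_t^2> = %.4f\n",
                x$chi_t, x$chi_t_err, x$M2_tot))
  if (x$unreliable) cat("  WARNING: flagged unreliable (sign)\n")
  invisible(x)
}

#' Trotter-step extrapolation of an observable
#'
#' Weighted least-squares fit of O(dtau) = O0 + c dtau^2 (+ d dtau^4)
#' and return of the dtau -> 0 intercept with its propagated standard
#' error. The leading Trotter error of the discrete-time algorithm is
#' quadratic, but at dtau W of order one (Hubbard-Stratonovich lambda
#' near 1) the quartic contamination is sizeable, so the quartic term is
#' included by default whenever three or more steps are available.
#'
#' @param dtau numeric vector of time steps (>= 3 distinct values)
#' @param values observable values at each step
#' @param errors optional standard errors; when given, the intercept
#'   error is the generalized-least-squares propagation of those errors
#' @param quartic include the dtau^4 term (default TRUE)
#' @return list with `value`, `err`, `curvature` (the dtau^2
#'   coefficient), and the coefficient vector `coef`
#' @export
extrapolate_dtau <- function(dtau, values, errors = NULL, quartic = TRUE) {
  stopifnot(length(dtau) == length(values))
  if (length(unique(dtau)) < 3)
    stop("need >= 3 distinct dtau values for a Trotter extrapolation")
  d2 <- dtau^2
  X <- cbind(1, d2, if (quartic && length(unique(dtau)) >= 3) d2^2)
  w <- if (is.null(errors)) rep(1, length(dtau)) else 1 / pmax(errors, 1e-300)^2
  XtWX <- crossprod(X * sqrt(w))
  b <- solve(XtWX, crossprod(X, w * values))
  if (is.null(errors)) {
    # unweighted: residual-based error (0 when the fit interpolates)
    dof <- length(values) - ncol(X)
    s2 <- if (dof > 0) sum((values - X %*% b)^2) / dof else 0
    err <- sqrt(s2 * solve(XtWX)[1, 1])
  } else {
    err <- sqrt(solve(XtWX)[1, 1])
  }
  list(value = b[1], err = err, curvature = b[2], coef = drop(b))
}

#' Trotter extrapolation across a list of QMC results
#'
#' Applies `extrapolate_dtau` to the standard scalar estimators of runs
#' that share the same physics but different time steps.
#'
#' @param results list of `qmc_result` objects (>= 3, distinct dtau)
#' @return data frame with one row per observable: value, err, curvature
#' @export
extrapolate_qmc_dtau <- function(results) {
  stopifnot(length(results) >= 3)
  dtau <- vapply(results, function(r) r$settings$dtau, 0)
  no <- results[[1]]$model$n_orb
  rows <- list()
  grab <- function(name, value_fn, err_fn) {
    v <- vapply(results, value_fn, 0)
    e <- vapply(results, err_fn, 0)
    ex <- extrapolate_dtau(dtau, v, e)
    rows[[length(rows) + 1L]] <<- data.frame(
      observable = name, value = ex$value, err = ex$err,
      curvature = ex$curvature)
  }
  for (v in seq_len(no)) {
    grab(sprintf("occ_%d", v), function(r) r$occ[v],
         function(r) pmax(r$occ_err[v], 1e-6))
    grab(sprintf("docc_%d", v), function(r) r$docc[v], function(r) r$docc_err[v])
  }
  if (!is.null(results[[1]]$chi_t))
    grab("chi_t", function(r) r$chi_t, function(r) r$chi_t_err)
  do.call(rbind, rows)
}
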
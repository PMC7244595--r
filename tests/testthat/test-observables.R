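test_that("effective moment convention maps spins to their Curie moments", {
  # free spin S: chi = g^2 S(S+1) muB^2 / (3 k_B T), M_eff = g sqrt(S(S+1))
  for (S in c(1 / 2, 1, 2)) {
    for (Tk in c(100, 300)) {
      chi <- 4 * S * (S + 1) / (3 * k_B * Tk)
      expect_equal(effective_moment(chi, Tk), 2 * sqrt(S * (S + 1)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(effective_moment(0, 300), 0)
  expect_error(effective_moment(-1, 300), "negative")
  expect_error(instantaneous_moment(-0.1), "negative")
})

test_that("curie_fit recovers exact and noisy generators", {
  # exact Curie data round-trips through the fit
  curve <- make_curie_dataset(4.9, c(100, 150, 200, 300, 450, 600))
  cf <- curie_fit(curve)
  expect_equal(cf$M_eff, 4.9, tolerance = 1e-10)
  expect_lt(cf$goodness, 1e-10)
  # effective_moment(curie_fit) is idempotent on exact Curie data
  expect_equal(effective_moment(cf$C / 300, 300), cf$M_eff, tolerance = 1e-10)
  # 5% noise: recovery within 2 sigma of the fit uncertainty budget
  devs <- vapply(1:20, function(s) {
    cn <- make_curie_dataset(4.9, c(100, 150, 200, 300, 450, 600),
                             noise = 0.05, seed = s)
    curie_fit(cn)$M_eff - 4.9
  }, 0)
  expect_lt(abs(mean(devs)), 2 * stats::sd(devs) / sqrt(length(devs)) + 0.02)
  expect_lt(stats::sd(devs), 0.15)
})

test_that("a two-regime crossover is detected and resolved piecewise", {
  Ts <- c(100, 140, 180, 220, 260, 340, 420, 500, 600, 700)
  two <- make_curie_dataset(2.1, Ts, T_star = 300, M_eff_high = 4.9)
  cf <- curie_fit(two, piecewise = TRUE)
  expect_true(cf$crossover)
  expect_equal(cf$M_eff_low, 2.1, tolerance = 1e-6)
  expect_equal(cf$M_eff_high, 4.9, tolerance = 1e-6)
  expect_equal(cf$T_star, 300, tolerance = 60)
  # single-regime data must not be flagged
  one <- make_curie_dataset(4.9, Ts)
  expect_false(isTRUE(curie_fit(one, piecewise = TRUE)$crossover))
})

test_that("chemical-potential tuning honors symmetry and the ED oracle", {
  # particle-hole symmetric single orbital: mu = eps_d + U/2 gives <n> = 1
  U <- 2
  m <- anderson_model(numeric(0), -0.3, matrix(0, 0, 1), U = U,
                      n_target = 1)
  tuned <- tune_mu(m, T_kelvin = 2000, solver = "ed", tol = 1e-4)
  # N(mu) is flat around the symmetric point, so mu is pinned only to
  # the resolution the occupation tolerance implies
  expect_lt(abs(tuned$mu - (-0.3 + U / 2)), 0.02)
  expect_equal(tuned$N, 1, tolerance = 2e-4)
  # noninteracting fixture at half filling: mu at the symmetric point
  m0 <- anderson_model(c(-1, 1), 0, matrix(c(0.4, 0.4), 2, 1), U = 0,
                       n_target = 3)
  t0 <- tune_mu(m0, T_kelvin = 1000, solver = "noninteracting", tol = 1e-5)
  expect_equal(t0$mu, 0, tolerance = 1e-3)
  # QMC-tuned mu agrees with ED-tuned mu within combined tolerance
  mi <- toy_1orb(U = 2, J = 0, mu = 0, V = 0.5, host = 0.4, eps_d = -1)
  mi$n_target <- 2
  ted <- tune_mu(mi, T_kelvin = 3000, solver = "ed", tol = 0.01)
  tqmc <- tune_mu(mi, T_kelvin = 3000, solver = "qmc", tol = 0.05,
                  qmc_args = list(grid = tau_grid(T_kelvin = 3000, L = 12),
                                  n_warmup = 50, n_sweeps = 600,
                                  n_bins = 4, seed = 2))
  expect_lt(abs(ted$mu - tqmc$mu), 0.15)
  expect_error(tune_mu(anderson_model(numeric(0), 50, matrix(0, 0, 1),
                                      U = 0, n_target = 2),
                       T_kelvin = 300, solver = "noninteracting",
                       max_expand = 1), "no bracket")
})

test_that("the noninteracting moment scan peaks where levels cross mu", {
  m <- anderson_model(c(-1, 0.6), 0.1, matrix(0, 2, 1), U = 0)
  sc <- moment_vs_mu_scan(m, 500, seq(-1.5, 1.2, by = 0.05),
                          solver = "noninteracting")
  peaks <- sc$mu[order(-sc$M_t)][1:3]
  expect_true(any(abs(peaks - (-1)) < 0.06))
  expect_true(any(abs(peaks - 0.6) < 0.06) || any(abs(peaks - 0.1) < 0.06))
  # far from every level the moment vanishes
  far <- moment_vs_mu_scan(m, 500, -8, solver = "noninteracting")
  expect_lt(far$M_t, 1e-6)
})

test_that("the moment map conserves the total and flags bad projections", {
  # Hund-coupled two-orbital impurity, strongly coupled half-filled host
  # level: the Fe moment dominates the total, so the AF-correlated host
  # site must come out with the opposite sign (ED cross-check above
  # establishes host total correlation < 0 < impurity total correlation)
  U <- 3; J <- 0.6
  shift <- (U + (U - 2 * J) + (U - 3 * J)) / 2
  m <- anderson_model(0, rep(-1.5 - shift, 2), matrix(0.8, 1, 2),
                      U = U, J = J)
  r <- run_qmc(m, tau_grid(beta = 6, L = 24), n_warmup = 200,
               n_sweeps = 4000, n_bins = 8, seed = 13)
  proj <- rbind(c(0, 1), c(1, 0), c(1, 0))  # host -> C1; orbitals -> Fe
  colnames(proj) <- c("Fe", "C1")
  map <- project_moment_density(r, proj)
  # bookkeeping identity: atomic moments sum to the total estimator
  expect_equal(sum(map$moment), sqrt(r$M2_tot), tolerance = 1e-8)
  # antiferromagnetic fixture: host site sign opposite to Fe sign
  expect_lt(map$moment[map$atom == "C1"] * map$moment[map$atom == "Fe"], 0)
  expect_error(project_moment_density(r, rbind(c(0.5, 0.4), c(1, 0), c(1, 0))),
               "sum to 1")
  expect_error(project_moment_density(r, proj[1:2, ]), "rows")
})

test_that("Fe-host correlations vanish for decoupled free hosts", {
  m <- toy_1orb(U = 0, J = 0, mu = 0, V = 0, host = c(-0.4, 0.7),
                eps_d = -1)
  r <- run_qmc(m, tau_grid(beta = 4, L = 8), n_warmup = 20, n_sweeps = 200,
               n_bins = 4, seed = 1)
  fh <- fe_host_correlation(r)
  expect_equal(fh$corr, c(0, 0), tolerance = 1e-10)
  # Kondo-like fixture: AF correlation grows as T drops (ED temperature sweep)
  mk <- toy_1orb(U = 2, J = 0, mu = 0, V = 0.8, host = 0, eps_d = -1)
  corr_T <- vapply(c(8000, 3000, 1200), function(Tk) {
    o <- ed_observables(ed_spectrum(mk), T_kelvin = Tk)
    o$mz_corr[2, 1]
  }, 0)
  expect_true(all(diff(corr_T) < 0))  # increasingly negative
  expect_lt(corr_T[3], 0)
})
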
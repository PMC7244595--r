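test_that("the free theory passes through the solver untouched", {
  m <- toy_1orb(U = 0, J = 0)
  grid <- tau_grid(beta = 2, L = 6)
  tab <- pair_table(m, grid)
  bath <- hemeqmc:::qmc_bath(m, grid)
  f <- hs_fields(nrow(tab), grid$L)
  G <- green_from_fields(bath, f, tab)
  expect_equal(G$up, bath$g0, tolerance = 1e-13)
  expect_equal(G$dn, bath$g0, tolerance = 1e-13)
  # U = 0 sweep: every flip accepted, G unchanged
  set.seed(1)
  sw <- sweep_reference(G, f, tab, grid$L, rule = "metropolis")
  expect_equal(sw$n_accept, 0L)  # lambda = 0 fields are skipped outright
  r <- run_qmc(m, grid, n_warmup = 5, n_sweeps = 40, n_bins = 4, seed = 1,
               measure_interval = 2)
  expect_equal(r$acceptance, 1)
  expect_equal(r$sign_avg, 1)
})

test_that("single flips match clean updates for every pair type", {
  set.seed(7)
  m <- anderson_model(0.3, c(-1.5, -0.8), matrix(c(0.4, 0.6), 1, 2),
                      U = 2, J = 0.45)
  grid <- tau_grid(beta = 2, L = 4)
  tab <- pair_table(m, grid)
  bath <- hemeqmc:::qmc_bath(m, grid)
  f <- hs_fields(nrow(tab), grid$L)
  G <- green_from_fields(bath, f, tab)
  for (p in seq_len(nrow(tab))) for (l in c(1, 3)) {
    pr <- propose_flip(G, f, tab, p, l, grid$L)
    res <- pr$apply()
    Gc <- green_from_fields(bath, res$fields, tab)
    expect_lt(max(abs(res$G$up - Gc$up), abs(res$G$dn - Gc$dn)), 1e-9)
    # ratio equals the from-scratch determinant ratio
    expect_equal(pr$R, exp(Gc$log_weight - G$log_weight) * Gc$sign * G$sign,
                 tolerance = 1e-9)
  }
})

test_that("exhaustive enumeration reproduces ED at small Trotter step", {
  m <- toy_1orb(U = 2, J = 0, mu = 0.1, V = 0.5, host = 0.4, eps_d = -1.2)
  ed <- ed_observables(ed_spectrum(m), beta = 1)
  en <- enumerate_hf(m, tau_grid(beta = 1, L = 10))  # dtau = 0.1
  expect_equal(en$sign_avg, 1)
  expect_lt(abs(en$occ_up - ed$occ_up[2]) / ed$occ_up[2], 1e-3)
  expect_lt(abs(en$docc - ed$docc) / ed$docc, 1e-3)
  # Trotter error shrinks quadratically: halving dtau -> ~4x closer
  en2 <- enumerate_hf(m, tau_grid(beta = 1, L = 5))
  err10 <- abs(en$docc - ed$docc); err5 <- abs(en2$docc - ed$docc)
  expect_gt(err5 / err10, 2.5)
})

test_that("compiled sweeps stay consistent with clean rebuilds", {
  m <- toy_1orb(U = 2, J = 0)
  grid <- tau_grid(beta = 4, L = 8)
  r <- run_qmc(m, grid, n_warmup = 100, n_sweeps = 100, n_bins = 4,
               seed = 5, clean_interval = 50)
  expect_lt(r$drift_max, 1e-8)
  expect_gt(r$acceptance, 0); expect_lt(r$acceptance, 1)
  expect_equal(r$sign_avg, 1)  # single orbital: no sign problem
})

test_that("the same seed reproduces a bit-identical result", {
  m <- atomic_2orb()
  grid <- tau_grid(beta = 2, L = 6)
  r1 <- run_qmc(m, grid, n_warmup = 20, n_sweeps = 80, n_bins = 4, seed = 42)
  r2 <- run_qmc(m, grid, n_warmup = 20, n_sweeps = 80, n_bins = 4, seed = 42)
  r1$settings <- r2$settings <- NULL
  expect_identical(r1, r2)
})

test_that("the atomic limit reproduces the four-state partition function", {
  # V = 0, U = 2, beta = 2: all terms commute, so no Trotter error at all
  e <- -0.6; U <- 2; beta <- 2
  m <- anderson_model(numeric(0), e, matrix(0, 0, 1), U = U, mu = 0)
  Z <- 1 + 2 * exp(-beta * e) + exp(-beta * (2 * e + U))
  docc_exact <- exp(-beta * (2 * e + U)) / Z
  occ_exact <- (exp(-beta * e) + exp(-beta * (2 * e + U))) / Z
  r <- run_qmc(m, tau_grid(beta = beta, L = 8), n_warmup = 200,
               n_sweeps = 20000, n_bins = 16, seed = 11,
               measure_hosts = FALSE)
  expect_within_sigma(r$docc, docc_exact, r$docc_err, 3, "docc")
  expect_within_sigma(r$occ, occ_exact, r$occ_err, 3, "occ")
})

test_that("spin symmetry and sign bookkeeping hold on an interacting run", {
  m <- atomic_2orb(U = 2, J = 0.45)
  r <- run_qmc(m, tau_grid(beta = 2, L = 8), n_warmup = 200,
               n_sweeps = 8000, n_bins = 16, seed = 3,
               measure_hosts = FALSE)
  for (v in 1:2)
    expect_within_sigma(r$occ_up[v], r$occ_dn[v],
                        sqrt(r$occ_up_err[v]^2 + r$occ_dn_err[v]^2) + 1e-4,
                        3.5, sprintf("spin symmetry orbital %d", v))
  expect_lte(abs(r$sign_avg), 1)
  ed <- ed_observables(ed_spectrum(m), beta = 2)
  for (v in 1:2)
    expect_within_sigma(r$docc[v], ed$docc[v],
                        sqrt(r$docc_err[v]^2) + 2e-3, 3, "atomic docc")
})

test_that("QMC matches ED within errors on a hybridized toy cluster", {
  m <- toy_1orb(U = 2, J = 0, mu = 0, V = 0.5, host = c(-0.3, 0.5),
                eps_d = -1)
  ed <- ed_observables(ed_spectrum(m), beta = 4)
  r <- run_qmc(m, tau_grid(beta = 4, L = 16), n_warmup = 300,
               n_sweeps = 12000, n_bins = 16, seed = 7, measure_tau = TRUE)
  # dtau = 0.25 Trotter bias allowance on top of statistical error
  expect_within_sigma(r$occ, (ed$occ_up + ed$occ_dn)[3] / 2,
                      r$occ_err + 3e-3, 3, "occ")
  expect_within_sigma(r$docc, ed$docc, r$docc_err + 4e-3, 3, "docc")
  expect_within_sigma(r$chi_t, ed$chi_t, r$chi_t_err + 0.06, 3, "chi_t")
  # conserved total S_z: the tau-integrated and equal-time estimators agree
  expect_within_sigma(r$chi_tau, r$chi_t,
                      sqrt(r$chi_t_err^2) + 0.02 * r$chi_t, 2, "chi_tau")
  # tau-resolved correlator is flat for a conserved total moment
  expect_lt(diff(range(r$tau_corr)) / mean(r$tau_corr), 0.05)
  # host correlations carry the Kondo-like antiferromagnetic sign
  expect_lt(r$fe_host_corr[1], 0)
})

test_that("Trotter extrapolation recovers generators and fits", {
  # exact quadratic input is recovered exactly
  d <- c(0.1, 0.2, 0.3)
  ex <- extrapolate_dtau(d, 1 + 0.1 * d^2)
  expect_equal(ex$value, 1, tolerance = 1e-10)
  expect_equal(ex$curvature, 0.1, tolerance = 1e-8)
  # constant series: identical constant, ~zero slope
  exc <- extrapolate_dtau(c(0.5, 0.25, 0.125), rep(0.7, 3),
                          errors = rep(0.01, 3))
  expect_equal(exc$value, 0.7, tolerance = 1e-10)
  expect_equal(exc$curvature, 0, tolerance = 1e-8)
  expect_error(extrapolate_dtau(c(0.1, 0.1, 0.2), rep(1, 3)), ">= 3 distinct")
  # extrapolated toy observable lands closer to ED than any single dtau
  # (up to its own statistical resolution)
  m <- toy_1orb(U = 2, J = 0, mu = 0, V = 0.5, host = 0.4, eps_d = -1)
  ed <- ed_observables(ed_spectrum(m), beta = 4)
  runs <- lapply(c(0.5, 0.25, 0.125), function(dt)
    run_qmc(m, tau_grid(beta = 4, dtau = dt), n_warmup = 200,
            n_sweeps = 15000, n_bins = 16, seed = 9,
            measure_hosts = FALSE))
  ex2 <- extrapolate_qmc_dtau(runs)
  k <- which(ex2$observable == "docc_1")
  single_errs <- vapply(runs, function(r) abs(r$docc - ed$docc), 0)
  expect_lt(abs(ex2$value[k] - ed$docc),
            min(single_errs) + 3 * ex2$err[k])
})
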
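test_that("model validation enforces the interaction constraints", {
  expect_error(anderson_model(0, -1, matrix(0.5, 1, 1), U = -1),
               "U must be")
  expect_error(anderson_model(0, -1, matrix(0.5, 1, 1), U = 2, J = 1.2),
               "J <= U/2", fixed = TRUE)
  expect_warning(anderson_model(0, -1, matrix(0.5, 1, 1), U = 3, J = 1.4),
                 "attractive")
  expect_error(anderson_model(c(0, 1), -1, matrix(0.5, 1, 1), U = 1),
               "hybridization must be")
  m <- anderson_model(0, -1, matrix(0.5, 1, 1), U = 4, J = 0.9)
  expect_equal(m$Uprime, 4 - 2 * 0.9)
  expect_equal(m$Udprime, 4 - 3 * 0.9)
})

test_that("one-body matrix is the documented arrowhead", {
  # decoupled level pinned at mu
  m0 <- anderson_model(numeric(0), 0.3, matrix(0, 0, 1), U = 0, mu = 0.3)
  expect_equal(one_body_matrix(m0), matrix(0, 1, 1))
  # direct transcription of a 1-host + 1-orbital model
  m <- anderson_model(1, -1, matrix(0.5, 1, 1), U = 0, mu = 0)
  expect_equal(one_body_matrix(m), matrix(c(1, 0.5, 0.5, -1), 2, 2))
  # heme-like fixture: eigenvalue sum equals the trace
  gen <- make_heme_like("deoxy", seed = 5)
  H <- one_body_matrix(gen$model)
  expect_equal(dim(H), c(65, 65))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(gen$model$host_energies - gen$model$mu) +
    sum(gen$model$impurity_energies - gen$model$mu)
  expect_equal(sum(ev), tr, tolerance = 1e-10)
  # host-host block stays diagonal
  expect_true(all(H[1:60, 1:60][upper.tri(matrix(0, 60, 60))] == 0))
})

test_that("pair table counts, couplings and HS constants are exact", {
  grid <- tau_grid(beta = 2, L = 8)
  for (no in 1:5) {
    m <- anderson_model(numeric(0), rep(-1, no), matrix(0, 0, no),
                        U = 4, J = 0.9)
    tab <- pair_table(m, grid)
    expect_equal(nrow(tab), no + 2 * no * (no - 1))
    expect_setequal(round(unique(tab$W), 10), round(unique(c(
      4, if (no > 1) c(4 - 1.8, 4 - 2.7))), 10))
  }
  m5 <- anderson_model(numeric(0), rep(-1, 5), matrix(0, 0, 5),
                       U = 4, J = 0.9)
  tab5 <- pair_table(m5, grid)
  expect_equal(nrow(tab5), 45)
  expect_equal(sort(unique(tab5$W)), c(1.3, 2.2, 4.0))
  # lambda closed form, pinned at dtau * W = 1
  g1 <- tau_grid(beta = 4, L = 8)  # dtau = 0.5, W = 2 -> dtau W = 1
  mt <- anderson_model(numeric(0), -1, matrix(0, 0, 1), U = 2)
  expect_equal(pair_table(mt, g1)$lambda, acosh(exp(0.5)), tolerance = 1e-14)
  # lambda = 0 iff W = 0
  mfree <- anderson_model(numeric(0), c(-1, 0), matrix(0, 0, 2), U = 0)
  expect_true(all(pair_table(mfree, grid)$lambda == 0))
})

test_that("tau grid bookkeeping is exact and warns about coarse steps", {
  g <- tau_grid(beta = 4, L = 16)
  expect_equal(g$dtau * g$L, g$beta)
  g2 <- tau_grid(T_kelvin = 300, dtau = 0.25)
  expect_equal(g2$beta, beta_from_T(300))
  expect_error(tau_grid(beta = 4, L = 1), "L must be")
  m <- anderson_model(numeric(0), -1, matrix(0, 0, 1), U = 4)
  expect_warning(tau_grid(beta = 4, L = 8, model = m), "Trotter")
})

test_that("bath propagator satisfies the free-level limits and sum rule", {
  grid <- tau_grid(beta = 4, L = 8)
  # decoupled level at mu: g(tau) = -1/2 for all tau in (0, beta); the
  # matrix entries with negative slice difference carry the antiperiodic
  # sign, +1/2
  m0 <- anderson_model(numeric(0), 0, matrix(0, 0, 1), U = 0)
  g00 <- bath_g0(m0, grid)$g0
  low <- g00[lower.tri(g00, diag = TRUE)]
  expect_equal(max(abs(low + 0.5)), 0, tolerance = 1e-14)
  expect_equal(max(abs(g00[upper.tri(g00)] - 0.5)), 0, tolerance = 1e-14)
  # occupation limits of the equal-time value g(0+) = n - 1:
  # far-empty level -> -1, far-filled level -> 0
  up <- anderson_model(numeric(0), 50, matrix(0, 0, 1), U = 0)
  dn <- anderson_model(numeric(0), -50, matrix(0, 0, 1), U = 0)
  expect_equal(bath_g0(up, grid)$g0[1, 1], -1, tolerance = 1e-12)
  expect_equal(bath_g0(dn, grid)$g0[1, 1], 0, tolerance = 1e-12)
  # discontinuity identity g(0+) + g(beta-) = -1 on a hybridized fixture
  m <- toy_1orb()
  es <- eigen(one_body_matrix(m), symmetric = TRUE)
  for (tautest in c(0)) {
    gp <- hemeqmc:::g_tau_sites(es, 4, 0, 3, 3)         # 0+
    gm <- hemeqmc:::g_tau_sites(es, 4, 4 - 1e-12, 3, 3)  # beta-
    expect_equal(gp + gm, matrix(-1), tolerance = 1e-9)
  }
  # antiperiodicity g(tau - beta) = -g(tau)
  gpos <- hemeqmc:::g_tau_sites(es, 4, 1.3, 3, 3)
  gneg <- hemeqmc:::g_tau_sites(es, 4, 1.3 - 4, 3, 3)
  expect_equal(gneg, -gpos, tolerance = 1e-12)
})

test_that("bath propagator matches the independent two-level formula", {
  m <- anderson_model(1, -1, matrix(0.5, 1, 1), U = 0)
  grid <- tau_grid(beta = 4, L = 16)
  g0 <- bath_g0(m, grid)$g0
  # independent evaluation from the 2x2 eigen-decomposition
  H <- matrix(c(1, 0.5, 0.5, -1), 2, 2)
  es <- eigen(H, symmetric = TRUE)
  gref <- function(tau) {
    s <- if (tau > 0 || tau == 0) 1 else -1
    if (tau <= 0 && tau != 0) tau <- tau + 4
    -s * sum(es$vectors[2, ]^2 * exp(-tau * es$values) /
               (1 + exp(-4 * es$values)))
  }
  for (i in c(1, 5, 16)) for (j in c(1, 9)) {
    expect_equal(g0[i, j], gref((i - j) * grid$dtau), tolerance = 1e-12)
  }
})

test_that("noninteracting density matches ED at U = 0 and obeys limits", {
  m <- toy_1orb(U = 0, J = 0)
  nd <- noninteracting_density(m, beta = 4)
  ed <- ed_observables(ed_spectrum(m), beta = 4)
  expect_equal(nd$site_occupations, ed$occ_up, tolerance = 1e-9)
  expect_equal(nd$N_total, ed$N_total, tolerance = 1e-9)
  # level at mu: half filling per spin; all levels far above: empty
  m0 <- anderson_model(numeric(0), 0, matrix(0, 0, 1), U = 0)
  expect_equal(noninteracting_density(m0, beta = 4)$site_occupations, 0.5)
  mh <- anderson_model(numeric(0), 100, matrix(0, 0, 1), U = 0)
  expect_equal(noninteracting_density(mh, beta = 4)$N_total, 0)
})

test_that("model config YAML round-trips bit-exactly", {
  gen <- make_heme_like("oxy", seed = 3)
  gen$model$mu <- 1 / 3  # non-representable decimal
  p1 <- file.path(tempdir(), "m1.yaml"); p2 <- file.path(tempdir(), "m2.yaml")
  write_model_config(gen$model, p1, grid = tau_grid(beta = 4, L = 16))
  rt <- read_model_config(p1)
  expect_identical(rt$model$hybridization, gen$model$hybridization)
  expect_identical(rt$model$host_energies, gen$model$host_energies)
  expect_identical(rt$model$mu, gen$model$mu)
  expect_equal(rt$grid$L, 16)
  write_model_config(rt$model, p2, grid = rt$grid)
  expect_identical(readLines(p1), readLines(p2))
})
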
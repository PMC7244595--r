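test_that("generators are pure functions of their seed", {
  m1 <- make_toy_cluster(1, 2, "kondo", seed = 5)
  m2 <- make_toy_cluster(1, 2, "kondo", seed = 5)
  expect_identical(m1, m2)
  g1 <- make_heme_like("deoxy", seed = 9)
  g2 <- make_heme_like("deoxy", seed = 9)
  expect_identical(g1, g2)
  # serialized configs are byte-identical for the same seed
  p1 <- file.path(tempdir(), "a.yaml"); p2 <- file.path(tempdir(), "b.yaml")
  write_model_config(g1$model, p1); write_model_config(g2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(make_toy_cluster(1, 2, "kondo"), "seed")
})

test_that("toy regimes carry their defining structure", {
  # symmetric: ED gives exact half filling per orbital
  ms <- make_toy_cluster(1, 2, "symmetric", seed = 3)
  obs <- ed_observables(ed_spectrum(ms), beta = 4)
  expect_equal(obs$occ_up[3] + obs$occ_dn[3], 1, tolerance = 1e-9)
  expect_equal(obs$N_total, 3, tolerance = 1e-9)
  # kondo at low T: impurity-host spin correlation is negative
  mk <- make_toy_cluster(1, 2, "kondo", seed = 4)
  ok <- ed_observables(ed_spectrum(mk), T_kelvin = 1500)
  host0 <- which.min(abs(mk$host_energies))
  expect_lt(ok$mz_corr[3, host0], 0)
  # free: no interaction at all
  expect_equal(make_toy_cluster(1, 2, "free", seed = 1)$U, 0)
  # ED-compatible by construction
  expect_s3_class(ed_spectrum(make_toy_cluster(2, 2, "kondo", seed = 8)),
                  "ed_spectrum")
})

test_that("heme-like fixtures carry the documented spectral structure", {
  for (variant in c("deoxy", "oxy")) {
    gen <- make_heme_like(variant, seed = 2)
    m <- gen$model
    expect_equal(m$n_orb, 5)
    expect_equal(m$n_host, 60)
    expect_equal(m$U, 4); expect_equal(m$J, 0.9)
    expect_equal(m$orbital_labels, c("xy", "xz", "yz", "z2", "x2y2"))
    # bonding pi state ~3 eV below the Fermi level
    expect_equal(m$host_energies[m$host_labels == "pi"], -3)
    # pi* manifolds: pi2* sits above pi1*; in the deoxy variant pi1*
    # straddles the Fermi level with ~0.3 eV width
    e1 <- m$host_energies[m$host_labels == "pi1*"]
    e2 <- m$host_energies[m$host_labels == "pi2*"]
    expect_gt(mean(e2), mean(e1))
    if (variant == "deoxy") {
      expect_equal(diff(range(e1)), 0.3, tolerance = 1e-9)
      expect_equal(mean(e1), 0, tolerance = 1e-9)
      expect_equal(mean(e2), 0.3, tolerance = 1e-9)
    } else {
      expect_true(all(e1 < 0) && all(e2 > 0.15))  # spin-gapped window
    }
    # pi-symmetry selection rule: pi* states couple to xz/yz only
    expect_true(all(m$hybridization[m$host_labels == "pi1*", c(1, 4, 5)] == 0))
    expect_true(all(m$hybridization[m$host_labels == "pi1*", 2:3] > 0))
    # projection rows sum to 1 and impurity rows sit on Fe
    expect_equal(rowSums(gen$projection), rep(1, 65), tolerance = 1e-12)
    expect_equal(unname(gen$projection[61:65, "Fe"]), rep(1, 5))
    # pi* weight lives on the 20 carbon sites
    Ccols <- grep("^C", colnames(gen$projection))
    p1rows <- which(m$host_labels == "pi1*")
    expect_equal(unname(rowSums(gen$projection[p1rows, Ccols, drop = FALSE])),
                 rep(1, length(p1rows)), tolerance = 1e-12)
  }
  # oxy adds the O2-derived acceptor within 0.15 eV of the Fermi level
  oxy <- make_heme_like("oxy", seed = 2)
  acc <- oxy$model$host_energies[oxy$model$host_labels == "O2*"]
  expect_length(acc, 1)
  expect_lt(abs(acc), 0.15)
  expect_true(any(grepl("^O", colnames(oxy$projection))))
  # half-filled pi1*, nearly empty pi2* (deoxy, noninteracting filling)
  deo <- make_heme_like("deoxy", seed = 2)
  nd <- noninteracting_density(deo$model, T_kelvin = 300)
  p1 <- which(deo$model$host_labels == "pi1*")
  p2 <- which(deo$model$host_labels == "pi2*")
  expect_gt(mean(nd$site_occupations[p1]), 0.3)
  expect_lt(mean(nd$site_occupations[p1]), 0.7)
  expect_lt(mean(nd$site_occupations[p2]), 0.3)
})

test_that("curie datasets invert through curie_fit", {
  cd <- make_curie_dataset(4.9, c(150, 300, 600))
  expect_equal(curie_fit(cd)$M_eff, 4.9, tolerance = 1e-12)
  # two-regime generator mirrors the crossover phenomenology
  Ts <- c(100, 150, 200, 250, 350, 450, 550, 650)
  two <- make_curie_dataset(2.1, Ts, T_star = 300, M_eff_high = 4.9)
  expect_equal(two$chi[1] * 3 * k_B * Ts[1], 2.1^2, tolerance = 1e-10)
  expect_equal(two$chi[8] * 3 * k_B * Ts[8], 4.9^2, tolerance = 1e-10)
  expect_error(make_curie_dataset(4.9, c(100, 200), noise = 0.1), "seed")
})
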
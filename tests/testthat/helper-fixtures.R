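# Shared small fixtures. Everything is built in code; no data files.

# 1 impurity orbital hybridized with one or two host levels; ED-sized.
toy_1orb <- function(U = 2, J = 0, mu = 0.1, V = 0.5,
                     host = c(-0.3, 0.5), eps_d = -1.2) {
  anderson_model(host_energies = host, impurity_energies = eps_d,
                 hybridization = matrix(V, length(host), 1),
                 U = U, J = J, mu = mu)
}

# atomic two-orbital model exercising every interaction channel
atomic_2orb <- function(U = 2, J = 0.45, mu = 0.2) {
  anderson_model(host_energies = numeric(0),
                 impurity_energies = c(-1.5, -0.8),
                 hybridization = matrix(0, 0, 2), U = U, J = J, mu = mu)
}

# impurity site indices in the ED site ordering (host first)
imp_sites <- function(model) model$n_host + seq_len(model$n_orb)

expect_within_sigma <- function(value, ref, err, nsigma, label = "value") {
  expect_lt(abs(value - ref), nsigma * max(err, 1e-12),
            label = sprintf("%s = %.5g vs ref %.5g (err %.2g)",
                            label, value, ref, err))
}
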
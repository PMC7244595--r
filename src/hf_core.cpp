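// Hirsch-Fye sweep kernel.
//
// Green's function convention g = -<T c c+> throughout, so the scalar
// determinant ratio for a single-site potential change gamma at site q is
// R = 1 + gamma (1 + G_qq) and the Sherman-Morrison update is
// G <- G - (gamma/R) (G_:q + e_q) G_q: .
// Uses R's RNG (unif_rand) so that set.seed() makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double scalar_ratio(const arma::mat& G, int q, double gamma) {
  return 1.0 + gamma * (1.0 + G(q, q));
}

static void rank1_update(arma::mat& G, int q, double gamma) {
  double R = scalar_ratio(G, q, gamma);
  arma::vec u = G.col(q);
  u(q) += 1.0;
  arma::rowvec v = G.row(q);
  G -= (gamma / R) * (u * v);
}

// One or more sweeps over all (pair, slice) fields.
// pairs: integer matrix, rows = pairs, columns (0-based orbitals,
// spins 0 = up / 1 = dn): orb_a, spin_a, orb_b, spin_b.
// fields: n_pairs x L matrix of +/-1 (modified copy returned).
// Layout of G indices: q = orb * L + slice.
// [[Rcpp::export]]
List hf_sweeps_cpp(arma::mat Gup, arma::mat Gdn, arma::imat fields,
                   const arma::imat& pairs, const arma::vec& lambda,
                   int L, int n_sweeps, bool heatbath, bool shuffle,
                   int sign) {
  const int np = pairs.n_rows;
  const int nfield = np * L;
  long n_acc = 0, n_prop = 0;
  std::vector<int> order(nfield);
  for (int i = 0; i < nfield; ++i) order[i] = i;

  for (int sw = 0; sw < n_sweeps; ++sw) {
    if (shuffle) {
      for (int i = nfield - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    }
    for (int k = 0; k < nfield; ++k) {
      const int p = order[k] % np;
      const int l = order[k] / np;
      const double lam = lambda(p);
      const int s_old = fields(p, l);
      if (lam == 0.0) {  // decoupled channel: flip is free, G untouched
        fields(p, l) = -s_old;
        ++n_prop; ++n_acc;
        continue;
      }
      const int qa = pairs(p, 0) * L + l;
      const int qb = pairs(p, 2) * L + l;
      const int sa = pairs(p, 1), sb = pairs(p, 3);
      const double ga = std::expm1(-2.0 * lam * s_old);
      const double gb = std::expm1(+2.0 * lam * s_old);
      double R;
      if (sa != sb) {
        const arma::mat& Ga = (sa == 0) ? Gup : Gdn;
        const arma::mat& Gb = (sb == 0) ? Gup : Gdn;
        R = scalar_ratio(Ga, qa, ga) * scalar_ratio(Gb, qb, gb);
      } else {
        const arma::mat& Gs = (sa == 0) ? Gup : Gdn;
        const double D11 = 1.0 + ga * (1.0 + Gs(qa, qa));
        const double D22 = 1.0 + gb * (1.0 + Gs(qb, qb));
        const double D12 = gb * Gs(qa, qb);
        const double D21 = ga * Gs(qb, qa);
        R = D11 * D22 - D12 * D21;
      }
      ++n_prop;
      const double aR = std::fabs(R);
      const double p_acc = heatbath ? aR / (1.0 + aR) : std::min(1.0, aR);
      if (p_acc >= 1.0 || unif_rand() < p_acc) {
        if (sa != sb) {
          rank1_update((sa == 0) ? Gup : Gdn, qa, ga);
          rank1_update((sb == 0) ? Gup : Gdn, qb, gb);
        } else {
          arma::mat& Gs = (sa == 0) ? Gup : Gdn;
          rank1_update(Gs, qa, ga);
          rank1_update(Gs, qb, gb);
        }
        fields(p, l) = -s_old;
        if (R < 0) sign = -sign;
        ++n_acc;
      }
    }
  }
  return List::create(_["Gup"] = Gup, _["Gdn"] = Gdn,
                      _["fields"] = fields, _["sign"] = sign,
                      _["n_accept"] = (double)n_acc,
                      _["n_prop"] = (double)n_prop);
}

// Clean (from-scratch) Dyson solve: A = I + (I + g0) diag(expm1(V)),
// G = A^{-1} g0; returns G with log|det A| and sign(det A).
// [[Rcpp::export]]
List hf_clean_cpp(const arma::mat& g0, const arma::vec& V) {
  const int n = g0.n_rows;
  arma::mat A = arma::eye(n, n);
  arma::rowvec em(n);
  for (int j = 0; j < n; ++j) em(j) = std::expm1(V(j));
  arma::mat IpG = arma::eye(n, n) + g0;
  A += IpG.each_row() % em;
  double val, s;
  arma::log_det(val, s, A);
  arma::mat G = arma::solve(A, g0);
  return List::create(_["G"] = G, _["logdet"] = val, _["sign"] = s);
}
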
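// Continuous-time Markov simulation of codon sites along a tree, one jump
// chain per (site, branch), recording realized synonymous / nonsynonymous
// substitution counts per branch. Uses R's RNG so results are reproducible
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {
arma::mat build_codon_q_sim(double kappa, double omega, const arma::vec& pi,
                            const arma::imat& type, double scale) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < n; ++j) {
      if (i == j) continue;
      double m;
      switch (type(i, j)) {
        case 1: m = 1.0; break;
        case 2: m = kappa; break;
        case 3: m = omega; break;
        case 4: m = kappa * omega; break;
        default: m = 0.0;
      }
      Q(i, j) = m * pi(j);
    }
  }
  Q.diag() = -arma::sum(Q, 1);
  double sc = scale > 0 ? scale : -arma::dot(pi, Q.diag());
  if (sc > 0) Q /= sc;
  return Q;
}
}  // namespace

// edge: preorder (parent, child) 1-based; root_state: 0-based codon per site;
// site_class: 0-based class index per site; omega_assign: nclass x nedge
// matrix of indices (0-based) into `omegas`. Returns node states (nnode x
// nsite) and per-edge syn/nonsyn counts.
// [[Rcpp::export]]
List sim_codon_cpp(const arma::imat& edge, const arma::vec& lens,
                   const arma::ivec& root_state, const arma::ivec& site_class,
                   const arma::imat& omega_assign, const arma::vec& omegas,
                   double kappa, const arma::vec& pi, const arma::imat& type,
                   int nnode, int root, double scale) {
  const arma::uword ne = edge.n_rows, nsite = root_state.n_elem,
                    ns = pi.n_elem, nom = omegas.n_elem;
  // per distinct omega: exit rates and cumulative jump distributions
  std::vector<arma::vec> exit(nom);
  std::vector<arma::mat> cumjump(nom);
  for (arma::uword w = 0; w < nom; ++w) {
    arma::mat Q = build_codon_q_sim(kappa, omegas(w), pi, type, scale);
    exit[w] = -Q.diag();
    arma::mat J(ns, ns, arma::fill::zeros);
    for (arma::uword i = 0; i < ns; ++i) {
      double r = exit[w](i);
      if (r <= 0) continue;
      double acc = 0.0;
      for (arma::uword j = 0; j < ns; ++j) {
        if (j != i) acc += Q(i, j) / r;
        J(i, j) = acc;
      }
    }
    cumjump[w] = J;
  }
  arma::imat states(nnode, nsite);
  states.row(root - 1) = root_state.t();
  arma::mat counts(ne, 2, arma::fill::zeros);  // syn, nonsyn
  for (arma::uword k = 0; k < ne; ++k) {
    int par = edge(k, 0), ch = edge(k, 1);
    double len = lens(k);
    for (arma::uword s = 0; s < nsite; ++s) {
      int st = states(par - 1, s);
      arma::uword w = (arma::uword)omega_assign(site_class(s), k);
      double tleft = len;
      while (tleft > 0) {
        double r = exit[w](st);
        if (r <= 0) break;
        double dt = R::exp_rand() / r;
        if (dt > tleft) break;
        tleft -= dt;
        double u = R::unif_rand();
        const arma::mat& J = cumjump[w];
        int nxt = st;
        for (arma::uword j = 0; j < ns; ++j) {
          if (u <= J(st, j)) { nxt = (int)j; break; }
        }
        if (nxt != st) {
          int tp = type(st, nxt);
          if (tp == 1 || tp == 2) counts(k, 0) += 1.0;
          else if (tp == 3 || tp == 4) counts(k, 1) += 1.0;
          st = nxt;
        }
      }
      states(ch - 1, s) = st;
    }
  }
  return List::create(_["states"] = states, _["counts"] = counts);
}

// Global Needleman-Wunsch similarity score on integer-coded sequences
// (match +1, mismatch 0, linear gap penalty). Used for reciprocal-best-hit
// scoring when translations differ in length.
// [[Rcpp::export]]
double nw_score_cpp(const arma::ivec& a, const arma::ivec& b, double gap) {
  const arma::uword n = a.n_elem, m = b.n_elem;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (arma::uword j = 0; j <= m; ++j) prev[j] = -gap * j;
  for (arma::uword i = 1; i <= n; ++i) {
    cur[0] = -gap * i;
    for (arma::uword j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (a(i - 1) == b(j - 1) ? 1.0 : 0.0);
      double up = prev[j] - gap;
      double left = cur[j - 1] - gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
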
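// Felsenstein pruning likelihoods for reversible nucleotide (GTR+Gamma) and
// codon (GY94-style) models, plus the branch-site (Model A) class likelihoods.
//
// Conventions shared with the R side:
//  - states are 0-based integer codes; -1 marks missing data (gap/ambiguity);
//  - `edge` is an ape-style postorder edge matrix (parent, child), 1-based node
//    ids with tips 1..ntip, so every child partial exists before its parent;
//  - branch lengths are expected substitutions per site (nucleotide) or per
//    codon (codon models), under a rate matrix scaled to unit flux at
//    stationarity;
//  - per-node scaling vectors guard against underflow; all site likelihoods
//    are returned on the log scale.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct REig {
  arma::mat U, Ui;
  arma::vec lam;
};

// Eigen-decompose a reversible rate matrix via its symmetrised form
// S = D^{1/2} Q D^{-1/2}, D = diag(pi). Then P(t) = U exp(lam t) Ui.
REig rev_eigen(const arma::mat& Q, const arma::vec& pi) {
  const arma::uword n = Q.n_rows;
  arma::vec sq = arma::sqrt(pi);
  arma::mat S(n, n);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      S(i, j) = Q(i, j) * sq(i) / sq(j);
  S = 0.5 * (S + S.t());
  REig e;
  arma::eig_sym(e.lam, e.U, S);
  e.Ui = e.U.t();
  e.Ui.each_row() %= sq.t();
  e.U.each_col() /= sq;
  return e;
}

arma::mat pmat(const REig& e, double t) {
  arma::mat P = e.U * arma::diagmat(arma::exp(e.lam * t)) * e.Ui;
  // numerical noise can leave tiny negatives
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

arma::mat tip_partial(const arma::imat& codes, int tip, arma::uword ns,
                      arma::uword npat) {
  arma::mat X(ns, npat);
  for (arma::uword p = 0; p < npat; ++p) {
    int s = codes(tip, p);
    if (s < 0) {
      X.col(p).ones();
    } else {
      X.col(p).zeros();
      X((arma::uword)s, p) = 1.0;
    }
  }
  return X;
}

// Postorder pruning pass. Fills per-node partials and per-node cumulative log
// scalers (each node's scaler covers its whole subtree).
void prune_pass(const arma::imat& codes, const arma::imat& edge,
                const std::vector<arma::mat>& P, int nnode, int ntip,
                std::vector<arma::mat>& part, std::vector<arma::rowvec>& lsc,
                arma::uword ns, arma::uword npat) {
  part.assign(nnode + 1, arma::mat());
  lsc.assign(nnode + 1, arma::rowvec());
  const arma::uword ne = edge.n_rows;
  for (arma::uword k = 0; k < ne; ++k) {
    int par = edge(k, 0), ch = edge(k, 1);
    arma::mat M;
    arma::rowvec sc;
    if (ch <= ntip) {
      M = P[k] * tip_partial(codes, ch - 1, ns, npat);
      sc.zeros(npat);
    } else {
      M = P[k] * part[ch];
      sc = lsc[ch];
    }
    if (part[par].n_elem == 0) {
      part[par] = M;
      lsc[par] = sc;
    } else {
      part[par] %= M;
      lsc[par] += sc;
    }
    // rescale parent so far
    arma::rowvec mx = arma::max(part[par], 0);
    mx.transform([](double x) { return x > 0.0 ? x : 1.0; });
    part[par].each_row() /= mx;
    lsc[par] += arma::log(mx);
  }
}

int find_root(const arma::imat& edge) {
  // postorder: last edge's parent is the root
  return edge(edge.n_rows - 1, 0);
}

arma::rowvec root_loglik(const arma::vec& pi, const arma::mat& rootpart,
                         const arma::rowvec& lsc) {
  arma::rowvec lik = pi.t() * rootpart;
  return arma::log(lik) + lsc;
}

// scale <= 0 requests self-normalisation (unit flux at stationarity);
// a positive scale divides the unscaled matrix by that flux instead, so a
// set of class matrices can share one scale.
arma::mat build_codon_q(double kappa, double omega, const arma::vec& pi,
                        const arma::imat& type, double scale = -1.0) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < n; ++j) {
      if (i == j) continue;
      double m;
      switch (type(i, j)) {
        case 1: m = 1.0; break;          // synonymous transversion
        case 2: m = kappa; break;        // synonymous transition
        case 3: m = omega; break;        // nonsynonymous transversion
        case 4: m = kappa * omega; break; // nonsynonymous transition
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

arma::mat build_gtr_q(const arma::vec& pi, const arma::vec& exch) {
  // exch order: AC, AG, AT, CG, CT, GT (states A=0, C=1, G=2, T=3)
  arma::mat Q(4, 4, arma::fill::zeros);
  int idx[4][4] = {{-1, 0, 1, 2}, {0, -1, 3, 4}, {1, 3, -1, 5}, {2, 4, 5, -1}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      if (i != j) Q(i, j) = exch(idx[i][j]) * pi(j);
  Q.diag() = -arma::sum(Q, 1);
  double scale = -arma::dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
arma::mat codon_q_cpp(double kappa, double omega, const arma::vec& pi,
                      const arma::imat& type) {
  return build_codon_q(kappa, omega, pi, type);
}

//' @noRd
// [[Rcpp::export]]
arma::mat gtr_q_cpp(const arma::vec& pi, const arma::vec& exch) {
  return build_gtr_q(pi, exch);
}

// Per-pattern log-likelihood under GTR with a discrete-rate mixture (equal
// weights). `rates` are the (mean-one) category rates.
// [[Rcpp::export]]
arma::vec nuc_site_loglik_cpp(const arma::imat& codes, const arma::imat& edge,
                              const arma::vec& lens, const arma::vec& pi,
                              const arma::vec& exch, const arma::vec& rates,
                              int nnode, int ntip) {
  const arma::uword npat = codes.n_cols, ne = edge.n_rows;
  arma::mat Q = build_gtr_q(pi, exch);
  REig e = rev_eigen(Q, pi);
  arma::vec sitelik(npat, arma::fill::zeros);
  // accumulate likelihoods on the natural scale via per-category max-logs
  arma::mat logcat(rates.n_elem, npat);
  for (arma::uword c = 0; c < rates.n_elem; ++c) {
    std::vector<arma::mat> P(ne);
    for (arma::uword k = 0; k < ne; ++k) P[k] = pmat(e, lens(k) * rates(c));
    std::vector<arma::mat> part;
    std::vector<arma::rowvec> lsc;
    prune_pass(codes, edge, P, nnode, ntip, part, lsc, 4, npat);
    int root = find_root(edge);
    logcat.row(c) = root_loglik(pi, part[root], lsc[root]);
  }
  arma::rowvec mx = arma::max(logcat, 0);
  arma::vec out(npat);
  for (arma::uword p = 0; p < npat; ++p) {
    double s = 0.0;
    for (arma::uword c = 0; c < rates.n_elem; ++c)
      s += std::exp(logcat(c, p) - mx(p));
    out(p) = mx(p) + std::log(s / rates.n_elem);
  }
  return out;
}

// Generic codon site-class log-likelihoods: one pruning pass per class, with
// class c using omega_bg[c] on all edges except the edges listed (1-based) in
// fg_edges, which use omega_fg[c]. Returns npat x nclass matrix of per-pattern
// log-likelihoods.
// [[Rcpp::export]]
arma::mat codon_class_loglik_cpp(const arma::imat& codes, const arma::imat& edge,
                                 const arma::vec& lens, const arma::vec& pi,
                                 const arma::imat& type, double kappa,
                                 const arma::vec& omega_bg,
                                 const arma::vec& omega_fg,
                                 const arma::ivec& fg_edges, int nnode,
                                 int ntip, double scale = -1.0) {
  const arma::uword npat = codes.n_cols, ne = edge.n_rows,
                    nclass = omega_bg.n_elem, ns = pi.n_elem;
  std::vector<bool> is_fg(ne, false);
  for (arma::uword i = 0; i < fg_edges.n_elem; ++i)
    if (fg_edges(i) >= 1) is_fg[fg_edges(i) - 1] = true;
  arma::mat out(npat, nclass);
  // cache eigendecompositions by omega value (indices, so the cache can
  // grow without invalidating references)
  std::vector<double> omv;
  std::vector<REig> ome;
  auto get_eig = [&](double w) -> size_t {
    for (size_t i = 0; i < omv.size(); ++i)
      if (omv[i] == w) return i;
    omv.push_back(w);
    ome.push_back(rev_eigen(build_codon_q(kappa, w, pi, type, scale), pi));
    return ome.size() - 1;
  };
  for (arma::uword c = 0; c < nclass; ++c) {
    size_t bi = get_eig(omega_bg(c)), fi = get_eig(omega_fg(c));
    const REig& eb = ome[bi];
    const REig& ef = ome[fi];
    std::vector<arma::mat> P(ne);
    for (arma::uword k = 0; k < ne; ++k)
      P[k] = pmat(is_fg[k] ? ef : eb, lens(k));
    std::vector<arma::mat> part;
    std::vector<arma::rowvec> lsc;
    prune_pass(codes, edge, P, nnode, ntip, part, lsc, ns, npat);
    int root = find_root(edge);
    out.col(c) = root_loglik(pi, part[root], lsc[root]).t();
  }
  return out;
}

// Branch-site Model A per-class site log-likelihoods, sharing pruning work
// between classes: classes (0, 2a) share the omega0 background pass and
// classes (1, 2b) share the neutral pass; the positively selected classes swap
// in the omega2 transition matrix on the single foreground edge via an
// above/below decomposition at that edge.
// Returns npat x 4 log-likelihoods, class order (0, 1, 2a, 2b).
// [[Rcpp::export]]
arma::mat modelA_site_loglik_cpp(const arma::imat& codes, const arma::imat& edge,
                                 const arma::vec& lens, const arma::vec& pi,
                                 const arma::imat& type, double kappa,
                                 double omega0, double omega2, int fg_edge,
                                 int nnode, int ntip, double scale = -1.0) {
  const arma::uword npat = codes.n_cols, ne = edge.n_rows, ns = pi.n_elem;
  const arma::uword fg = (arma::uword)(fg_edge - 1);
  REig e2 = rev_eigen(build_codon_q(kappa, omega2, pi, type, scale), pi);
  arma::mat Pfg2 = pmat(e2, lens(fg));
  int root = find_root(edge);
  int fg_par = edge(fg, 0), fg_ch = edge(fg, 1);

  // parent pointers and children lists for the above-walk
  std::vector<int> parent(nnode + 1, 0);
  std::vector<std::vector<arma::uword>> child_edges(nnode + 1);
  for (arma::uword k = 0; k < ne; ++k) {
    parent[edge(k, 1)] = edge(k, 0);
    child_edges[edge(k, 0)].push_back(k);
  }
  // path of nodes from root down to fg_par
  std::vector<int> path;
  for (int x = fg_par; x != root; x = parent[x]) path.push_back(x);
  path.push_back(root);
  std::reverse(path.begin(), path.end());

  arma::mat out(npat, 4);
  double wb[2] = {omega0, 1.0};
  for (int b = 0; b < 2; ++b) {
    REig eb = rev_eigen(build_codon_q(kappa, wb[b], pi, type, scale), pi);
    std::vector<arma::mat> P(ne);
    for (arma::uword k = 0; k < ne; ++k) P[k] = pmat(eb, lens(k));
    std::vector<arma::mat> part;
    std::vector<arma::rowvec> lsc;
    prune_pass(codes, edge, P, nnode, ntip, part, lsc, ns, npat);
    out.col(b) = root_loglik(pi, part[root], lsc[root]).t();

    // above-walk: G at each path node = partial for everything outside the
    // subtree hanging below the next path edge, root frequencies folded in
    arma::mat G(ns, npat);
    G.each_col() = pi;
    arma::rowvec gsc(npat, arma::fill::zeros);
    for (size_t s = 0; s < path.size(); ++s) {
      int x = path[s];
      // edge leading further down the path (or the fg edge itself at the end)
      arma::uword next_edge = fg;
      if (s + 1 < path.size()) {
        int y = path[s + 1];
        for (arma::uword k : child_edges[x])
          if (edge(k, 1) == y) next_edge = k;
      }
      for (arma::uword k : child_edges[x]) {
        if (k == next_edge && (s + 1 < path.size() || k == fg)) continue;
        int c = edge(k, 1);
        if (c <= ntip) {
          G %= P[k] * tip_partial(codes, c - 1, ns, npat);
        } else {
          G %= P[k] * part[c];
          gsc += lsc[c];
        }
      }
      if (s + 1 < path.size()) {
        int y = path[s + 1];
        arma::uword k = next_edge;
        G = P[k].t() * G;  // reversible: P' folding downward uses transpose
        (void)y;
      }
      arma::rowvec mx = arma::max(G, 0);
      mx.transform([](double v) { return v > 0.0 ? v : 1.0; });
      G.each_row() /= mx;
      gsc += arma::log(mx);
    }
    // combine with the below partial of the fg child under omega2
    arma::mat below;
    arma::rowvec bsc(npat, arma::fill::zeros);
    if (fg_ch <= ntip) {
      below = Pfg2 * tip_partial(codes, fg_ch - 1, ns, npat);
    } else {
      below = Pfg2 * part[fg_ch];
      bsc = lsc[fg_ch];
    }
    arma::rowvec lik = arma::sum(G % below, 0);
    out.col(2 + b) = (arma::log(lik) + gsc + bsc).t();
  }
  return out;
}

// Two-sequence codon log-likelihood from pattern counts: patterns are pairs
// (ia, ib) of 0-based codon states with multiplicities cnt.
// [[Rcpp::export]]
double codon_pair_loglik_cpp(const arma::ivec& ia, const arma::ivec& ib,
                             const arma::vec& cnt, const arma::vec& pi,
                             const arma::imat& type, double kappa,
                             double omega, double t) {
  arma::mat Q = build_codon_q(kappa, omega, pi, type);
  REig e = rev_eigen(Q, pi);
  arma::mat P = pmat(e, t);
  double ll = 0.0;
  for (arma::uword k = 0; k < ia.n_elem; ++k) {
    double v = pi(ia(k)) * P(ia(k), ib(k));
    ll += cnt(k) * std::log(v > 0 ? v : 1e-300);
  }
  return ll;
}

// Transition probability matrix for a reversible rate matrix (utility).
// [[Rcpp::export]]
arma::mat rev_pmat_cpp(const arma::mat& Q, const arma::vec& pi, double t) {
  REig e = rev_eigen(Q, pi);
  return pmat(e, t);
}
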
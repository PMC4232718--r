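// Felsenstein pruning over codon states, and transition-matrix
// construction from a cached spectral decomposition. The 61-state pruning
// recursion is the hot loop of every model fit, hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build P(t) = L diag(exp(lambda t)) R for each edge, clipping rounding
// negatives at 0. L and R come from the pi-symmetrized eigendecomposition
// of the generator (L = D^-1/2 V, R = V' D^1/2).
// [[Rcpp::export(name = ".cpp_transition_cubes")]]
arma::cube cpp_transition_cubes(const arma::mat& L, const arma::mat& R,
                                const arma::vec& lambda,
                                const arma::vec& t) {
  const arma::uword n = L.n_rows, E = t.n_elem;
  arma::cube P(n, n, E);
  for (arma::uword e = 0; e < E; ++e) {
    arma::mat M = L * arma::diagmat(arma::exp(lambda * t(e))) * R;
    M.for_each([](arma::mat::elem_type& x) { if (x < 0) x = 0; });
    P.slice(e) = M;
  }
  return P;
}

// Pruning log-likelihood per site pattern for one site class.
// edge: E x 2 matrix (1-based ape node ids), postorder row order.
// tip_states: ntip x npat, 0-based sense-codon state, -1 = missing.
// P: n x n x E cube, slice e = transition matrix of edge row e.
// pi: root (stationary) frequencies.
// Returns vector of npat per-pattern log-likelihoods.
// [[Rcpp::export(name = ".cpp_prune_loglik")]]
arma::vec cpp_prune_loglik(const arma::imat& edge, int ntip,
                           const arma::imat& tip_states,
                           const arma::cube& P, const arma::vec& pi) {
  const arma::uword E = edge.n_rows;
  const arma::uword npat = tip_states.n_cols;
  const arma::uword n = P.n_rows;
  int nnodes = ntip;
  for (arma::uword e = 0; e < E; ++e) {
    if (edge(e, 0) > nnodes) nnodes = edge(e, 0);
    if (edge(e, 1) > nnodes) nnodes = edge(e, 1);
  }
  std::vector<arma::mat> partial(nnodes + 1);
  std::vector<bool> have(nnodes + 1, false);
  arma::vec logscale(npat, arma::fill::zeros);
  int root = edge(E - 1, 0);  // postorder: last edge's parent is the root

  for (arma::uword e = 0; e < E; ++e) {
    const int ch = edge(e, 1), pa = edge(e, 0);
    arma::mat contrib(n, npat);
    const arma::mat& Pe = P.slice(e);
    if (ch <= ntip) {
      arma::vec rs = arma::sum(Pe, 1);  // row sums, for missing tips
      for (arma::uword j = 0; j < npat; ++j) {
        const int s = tip_states(ch - 1, j);
        if (s < 0) contrib.col(j) = rs;
        else       contrib.col(j) = Pe.col(s);
      }
    } else {
      // scale the completed child partial before propagating
      arma::mat& pc = partial[ch];
      for (arma::uword j = 0; j < npat; ++j) {
        double m = pc.col(j).max();
        if (m <= 0) m = 1e-300;  // fully impossible pattern guard
        pc.col(j) /= m;
        logscale(j) += std::log(m);
      }
      contrib = Pe * pc;
    }
    if (!have[pa]) { partial[pa] = contrib; have[pa] = true; }
    else           { partial[pa] %= contrib; }
  }

  arma::vec out(npat);
  for (arma::uword j = 0; j < npat; ++j) {
    double lik = arma::dot(pi, partial[root].col(j));
    out(j) = (lik > 0 ? std::log(lik) : -1e300) + logscale(j);
  }
  return out;
}
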
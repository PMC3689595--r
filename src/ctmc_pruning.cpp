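// Felsenstein pruning for an n-state continuous-time Markov model of
// discrete traits on a rooted binary tree.  Called with the tree's edge
// matrix in ape "postorder" order so parents always follow their children.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// edge: (nedge x 2) 1-based node indices as in ape (tips 1..ntip, root
// ntip+1); elen: branch lengths; tip_state: 1-based state index per tip;
// Q: k x k generator; prior: root state prior.
// [[Rcpp::export(name = ".ctmc_loglik_cpp", rng = false)]]
double ctmc_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                       IntegerVector tip_state, arma::mat Q,
                       arma::vec prior) {
  const int k = Q.n_rows;
  const int nedge = edge.nrow();
  const int nnode = ntip + ntip; // >= total nodes for a rooted binary tree
  arma::mat part(nnode + 2, k);
  std::vector<bool> seen(nnode + 2, false);
  double logscale = 0.0;

  for (int i = 0; i < ntip; ++i) {
    part.row(i).zeros();
    part(i, tip_state[i] - 1) = 1.0;
    seen[i] = true;
  }
  int root = edge(nedge - 1, 0) - 1;
  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    arma::mat P = arma::expmat(Q * elen[e]);
    arma::rowvec contrib = part.row(child) * P.t(); // sum_j P(i->j) L_j
    if (!seen[parent]) {
      part.row(parent).ones();
      seen[parent] = true;
    }
    part.row(parent) %= contrib;
    // rescale to avoid underflow on deep trees
    double m = part.row(parent).max();
    if (m > 0 && m < 1e-200) {
      part.row(parent) /= m;
      logscale += std::log(m);
    }
  }
  double lik = arma::dot(part.row(root).t(), prior);
  if (lik <= 0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale;
}
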
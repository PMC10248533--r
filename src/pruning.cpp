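// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Felsenstein pruning kernels.  Node numbering follows ape conventions:
// tips 1..n_tip, internal nodes n_tip+1..n_node.  `children` maps every
// node to its child nodes (empty for tips); `postorder` lists internal
// nodes so that children precede parents.  `P` holds, for every non-root
// node v, the transition matrix of the edge above v in slice v-1.
// `tip_states` is n_pat x n_tip with 1-based state indices, 0 = missing
// (gap/ambiguous -> partial vector of ones).

// [[Rcpp::export]]
arma::cube cpp_down_partials(const List& children,
                             const IntegerVector& postorder,
                             const arma::cube& P,
                             const IntegerMatrix& tip_states,
                             int n_states) {
  const int n_pat = tip_states.nrow();
  const int n_tip = tip_states.ncol();
  const int n_node = children.size();
  arma::cube L(n_states, n_pat, n_node, arma::fill::ones);
  for (int t = 0; t < n_tip; ++t) {
    for (int s = 0; s < n_pat; ++s) {
      int st = tip_states(s, t);
      if (st > 0) {
        for (int k = 0; k < n_states; ++k) L(k, s, t) = 0.0;
        L(st - 1, s, t) = 1.0;
      }
    }
  }
  for (int ii = 0; ii < postorder.size(); ++ii) {
    int v = postorder[ii] - 1;
    IntegerVector ch = children[v];
    arma::mat acc(n_states, n_pat, arma::fill::ones);
    for (int c = 0; c < ch.size(); ++c) {
      int w = ch[c] - 1;
      acc %= P.slice(w) * L.slice(w);
    }
    L.slice(v) = acc;
  }
  return L;
}

// Total log-likelihood with per-node rescaling (safe for larger trees).
// [[Rcpp::export]]
double cpp_tree_loglik(const List& children,
                       const IntegerVector& postorder,
                       const arma::cube& P,
                       const IntegerMatrix& tip_states,
                       const arma::vec& pi,
                       const arma::vec& weights,
                       int root) {
  const int n_pat = tip_states.nrow();
  const int n_tip = tip_states.ncol();
  const int n_node = children.size();
  const int n_states = (int) pi.n_elem;
  arma::cube L(n_states, n_pat, n_node, arma::fill::ones);
  arma::vec logscale(n_pat, arma::fill::zeros);
  for (int t = 0; t < n_tip; ++t) {
    for (int s = 0; s < n_pat; ++s) {
      int st = tip_states(s, t);
      if (st > 0) {
        for (int k = 0; k < n_states; ++k) L(k, s, t) = 0.0;
        L(st - 1, s, t) = 1.0;
      }
    }
  }
  for (int ii = 0; ii < postorder.size(); ++ii) {
    int v = postorder[ii] - 1;
    IntegerVector ch = children[v];
    arma::mat acc(n_states, n_pat, arma::fill::ones);
    for (int c = 0; c < ch.size(); ++c) {
      int w = ch[c] - 1;
      acc %= P.slice(w) * L.slice(w);
    }
    // rescale per pattern
    arma::rowvec mx = arma::max(acc, 0);
    for (int s = 0; s < n_pat; ++s) {
      double m = mx(s);
      if (m > 0 && m < 1e-100) {
        acc.col(s) /= m;
        logscale(s) += std::log(m);
      }
    }
    L.slice(v) = acc;
  }
  arma::rowvec site = pi.t() * L.slice(root - 1);
  double ll = 0.0;
  for (int s = 0; s < n_pat; ++s)
    ll += weights(s) * (std::log(site(s)) + logscale(s));
  return ll;
}
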
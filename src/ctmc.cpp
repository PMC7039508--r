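// Felsenstein pruning log-likelihood for a k-state continuous-time Markov
// chain on a rooted tree. Transition probabilities P(t) = exp(Q t) are
// built from one eigendecomposition of Q per call (Q is tiny: k x k), with
// a per-edge Pade expmat fallback when Q is defective or ill-conditioned.
// Per-node rescaling guards against underflow on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double ctmc_loglik_cpp(const arma::imat& edge,
                       const arma::vec& edge_length,
                       const arma::ivec& tip_states,
                       const int n_tip,
                       const int n_node,
                       const arma::mat& Q,
                       const arma::vec& root_prior) {
  const int k = Q.n_rows;
  const int n_edge = edge.n_rows;
  const int n_all = n_tip + n_node;

  // eigendecomposition route for P(t)
  cx_vec eval;
  cx_mat evec, evec_inv;
  bool have_eig = eig_gen(eval, evec, Q);
  if (have_eig) {
    cx_mat inv_try;
    if (inv(inv_try, evec) && rcond(evec) > 1e-10) {
      evec_inv = inv_try;
    } else {
      have_eig = false;
    }
  }

  mat L(n_all, k, fill::ones);
  vec logscale(n_all, fill::zeros);
  for (int i = 0; i < n_tip; ++i) {
    L.row(i).zeros();
    L(i, tip_states(i) - 1) = 1.0;
  }

  mat P(k, k);
  // edges must be in postorder: children resolved before their parent
  for (int e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const double t = edge_length(e);
    if (have_eig) {
      cx_mat Pc = evec * diagmat(exp(eval * t)) * evec_inv;
      P = real(Pc);
      P.elem(find(P < 0)).zeros();
    } else {
      P = expmat(Q * t);
    }
    vec v = P * L.row(child).t();
    L.row(parent) %= v.t();
    logscale(parent) += logscale(child);
    double m = L.row(parent).max();
    if (m <= 0) return -std::numeric_limits<double>::infinity();
    L.row(parent) /= m;
    logscale(parent) += std::log(m);
  }

  const int root = n_tip;  // root node number is n_tip + 1 (1-based)
  double lik = dot(L.row(root).t(), root_prior);
  if (lik <= 0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale(root);
}
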
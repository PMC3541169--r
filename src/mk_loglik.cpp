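// Felsenstein pruning for a k-state continuous-time Markov chain on a
// rooted tree.  Called with edges in ape "postorder" so every child row
// precedes its parent's own child row; polytomies need no special casing.
//
// Per-branch transition probabilities come from one eigendecomposition of
// the generator per call (P(t) L = V exp(D t) V^-1 L, two small matvecs per
// edge) with a scaling-and-squaring fallback when Q is numerically
// defective.  Partial likelihoods are rescaled per edge to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double mk_loglik_cpp(const arma::imat& edge,
                     const arma::vec& edge_length,
                     const arma::mat& tip_like,
                     const arma::mat& Q,
                     const arma::vec& root_prior,
                     int n_tip,
                     int root) {
  const uword k = Q.n_rows;
  const uword n_edge = edge.n_rows;
  const uword n_node = tip_like.n_rows + n_edge + 1;  // generous upper bound

  mat L(k, n_node, fill::ones);
  for (uword i = 0; i < (uword)n_tip; ++i)
    L.col(i) = tip_like.row(i).t();

  cx_vec eigval;
  cx_mat eigvec, vinv;
  bool use_eigen = eig_gen(eigval, eigvec, Q);
  if (use_eigen) {
    cx_mat vi;
    use_eigen = inv(vi, eigvec);
    if (use_eigen) {
      vinv = vi;
      mat recon = real(eigvec * diagmat(eigval) * vinv);
      double scale = 1.0 + abs(Q).max();
      if (abs(recon - Q).max() > 1e-8 * scale) use_eigen = false;
    }
  }

  double log_scale = 0.0;
  for (uword e = 0; e < n_edge; ++e) {
    uword parent = (uword)edge(e, 0) - 1;
    uword child  = (uword)edge(e, 1) - 1;
    double t = edge_length(e);

    vec lc = L.col(child);
    double mx = lc.max();
    if (mx <= 0.0) return R_NegInf;  // impossible data under the model
    lc /= mx;
    log_scale += std::log(mx);

    vec msg(k);
    if (use_eigen) {
      cx_vec w = vinv * cx_vec(lc, vec(k, fill::zeros));
      w %= exp(eigval * t);
      msg = real(eigvec * w);
    } else {
      msg = expmat(Q * t) * lc;
    }
    msg.clamp(0.0, datum::inf);
    L.col(parent) %= msg;
  }

  double lik = dot(root_prior, L.col((uword)root - 1));
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}
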
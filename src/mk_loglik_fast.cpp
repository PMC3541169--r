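// Specialized pruning kernels for the correlated-evolution fits.
//
// mk_loglik4_cpp: 4-state pruning with one eigendecomposition per call and
// hand-rolled complex 4-vector propagation per edge (the ML search calls
// this thousands of times per fit, so allocations are kept out of the edge
// loop).  Falls back to scaling-and-squaring when Q is numerically
// defective.
//
// binary_loglik2_cpp: 2-state pruning with the closed-form transition
// probabilities of the binary chain, used by the factorized
// independent-model fit.

#include <RcppArmadillo.h>
#include <complex>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double mk_loglik4_cpp(const arma::imat& edge,
                      const arma::vec& edge_length,
                      const arma::mat& tip_like,
                      const arma::mat& Q,
                      int n_tip,
                      int root) {
  const uword n_edge = edge.n_rows;
  const uword n_node = tip_like.n_rows + n_edge + 1;

  mat L(4, n_node, fill::ones);
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
      if (abs(recon - Q).max() > 1e-8 * (1.0 + abs(Q).max()))
        use_eigen = false;
    }
  }

  std::complex<double> V[4][4], W[4][4], lam[4];
  if (use_eigen) {
    for (int i = 0; i < 4; ++i) {
      lam[i] = eigval(i);
      for (int j = 0; j < 4; ++j) {
        V[i][j] = eigvec(i, j);
        W[i][j] = vinv(i, j);
      }
    }
  }

  double log_scale = 0.0;
  for (uword e = 0; e < n_edge; ++e) {
    uword parent = (uword)edge(e, 0) - 1;
    uword child  = (uword)edge(e, 1) - 1;
    double t = edge_length(e);

    double lc[4];
    double mx = 0.0;
    for (int i = 0; i < 4; ++i) {
      lc[i] = L(i, child);
      if (lc[i] > mx) mx = lc[i];
    }
    if (mx <= 0.0) return R_NegInf;
    for (int i = 0; i < 4; ++i) lc[i] /= mx;
    log_scale += std::log(mx);

    double msg[4];
    if (use_eigen) {
      std::complex<double> w[4];
      for (int j = 0; j < 4; ++j) {
        std::complex<double> s(0.0, 0.0);
        for (int i = 0; i < 4; ++i) s += W[j][i] * lc[i];
        w[j] = s * std::exp(lam[j] * t);
      }
      for (int i = 0; i < 4; ++i) {
        std::complex<double> s(0.0, 0.0);
        for (int j = 0; j < 4; ++j) s += V[i][j] * w[j];
        msg[i] = s.real() > 0.0 ? s.real() : 0.0;
      }
    } else {
      mat P = expmat(Q * t);
      for (int i = 0; i < 4; ++i) {
        double s = 0.0;
        for (int j = 0; j < 4; ++j) s += P(i, j) * lc[j];
        msg[i] = s > 0.0 ? s : 0.0;
      }
    }
    for (int i = 0; i < 4; ++i) L(i, parent) *= msg[i];
  }

  double lik = 0.0;
  for (int i = 0; i < 4; ++i) lik += 0.25 * L(i, (uword)root - 1);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}

// [[Rcpp::export]]
double binary_loglik2_cpp(const arma::imat& edge,
                          const arma::vec& edge_length,
                          const arma::ivec& tip_state,
                          double q01, double q10,
                          int n_tip,
                          int root) {
  const uword n_edge = edge.n_rows;
  const uword n_node = (uword)tip_state.n_elem + n_edge + 1;

  mat L(2, n_node, fill::ones);
  for (uword i = 0; i < (uword)n_tip; ++i) {
    L(0, i) = tip_state(i) == 0 ? 1.0 : 0.0;
    L(1, i) = tip_state(i) == 1 ? 1.0 : 0.0;
  }

  const double s = q01 + q10;
  const double pi1 = s > 0.0 ? q01 / s : 0.0;
  double log_scale = 0.0;

  for (uword e = 0; e < n_edge; ++e) {
    uword parent = (uword)edge(e, 0) - 1;
    uword child  = (uword)edge(e, 1) - 1;
    double t = edge_length(e);

    double l0 = L(0, child), l1 = L(1, child);
    double mx = l0 > l1 ? l0 : l1;
    if (mx <= 0.0) return R_NegInf;
    l0 /= mx; l1 /= mx;
    log_scale += std::log(mx);

    double m0, m1;
    if (s <= 0.0) {
      m0 = l0; m1 = l1;
    } else {
      double d = std::exp(-s * t);
      // P(0->1) = pi1 (1 - e^{-st}), P(1->0) = (1-pi1)(1 - e^{-st})
      double p01 = pi1 * (1.0 - d);
      double p10 = (1.0 - pi1) * (1.0 - d);
      m0 = (1.0 - p01) * l0 + p01 * l1;
      m1 = p10 * l0 + (1.0 - p10) * l1;
    }
    L(0, parent) *= m0;
    L(1, parent) *= m1;
  }

  double lik = 0.5 * (L(0, (uword)root - 1) + L(1, (uword)root - 1));
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}
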
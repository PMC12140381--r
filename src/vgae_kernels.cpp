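// Fused inner-product decoder loss/gradient for the variational graph
// autoencoder. The decoder scores every spot pair by sigmoid(h_i . h_j)
// and is trained against the self-looped adjacency with positive-class
// reweighting; the N x N logit matrix is the hot spot of training. Both
// the logits and the binary target are symmetric, so the kernel touches
// only the upper triangle, derives sigmoid and softplus from a single
// exp per pair, and uses dL/dH = 2 * scale * G * H (G symmetric) with a
// single GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted BCE between sigmoid(H H^T) and the binary target Ã (sparse,
// symmetric, self-loops included). pos_weight multiplies the positive
// class; loss and gradient are scaled by norm / N^2.
// Returns list(loss, grad) with grad = d loss / d H.
// [[Rcpp::export]]
List vgae_recon_loss_grad(const arma::mat& H, const arma::sp_mat& A_tilde,
                          double pos_weight, double norm,
                          bool want_grad = true) {
  const arma::uword n = H.n_rows;
  arma::mat logits = H * H.t();

  // elementwise pass over the upper triangle (incl. diagonal): negatives
  double loss = 0.0;
  arma::mat G;
  if (want_grad) G.set_size(n, n);
  for (arma::uword j = 0; j < n; ++j) {
    const double* col = logits.colptr(j);
    double* gcol = want_grad ? G.colptr(j) : nullptr;
    for (arma::uword i = 0; i <= j; ++i) {
      const double x = col[i];
      // t = exp(-|x|); softplus(x) = max(x, 0) + log1p(t);
      // sigmoid(x) = (x >= 0) ? 1/(1+t) : t/(1+t)
      const double t = std::exp(-std::abs(x));
      const double sp = (x > 0 ? x : 0.0) + std::log1p(t);
      loss += (i == j) ? sp : 2.0 * sp;
      if (want_grad) {
        const double sg = (x >= 0) ? 1.0 / (1.0 + t) : t / (1.0 + t);
        gcol[i] = sg;
      }
    }
  }
  // correct the positive entries (Ã is symmetric; visit upper half once)
  for (arma::sp_mat::const_iterator it = A_tilde.begin(); it != A_tilde.end(); ++it) {
    const arma::uword i = it.row(), j = it.col();
    if (i > j) continue;
    const double x = logits(i, j);
    const double t = std::exp(-std::abs(x));
    const double sp_pos = (x < 0 ? -x : 0.0) + std::log1p(t);  // softplus(-x)
    const double sp_neg = (x > 0 ? x : 0.0) + std::log1p(t);   // softplus(x)
    loss += (i == j) ? (pos_weight * sp_pos - sp_neg)
                     : 2.0 * (pos_weight * sp_pos - sp_neg);
    if (want_grad) {
      const double sg = (x >= 0) ? 1.0 / (1.0 + t) : t / (1.0 + t);
      G(i, j) = pos_weight * (sg - 1.0);
    }
  }
  const double scale = norm / double(n * n);
  loss *= scale;
  if (!want_grad) return List::create(Named("loss") = loss);
  G = arma::symmatu(G);
  arma::mat dH = (2.0 * scale) * (G * H);
  return List::create(Named("loss") = loss, Named("grad") = dH);
}
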
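#include <Rcpp.h>
using namespace Rcpp;

// Per-block composite log-likelihood contributions in the eigenbasis of R.
//
// For a block with LD matrix R = U diag(d) U', the model covariance of the
// stacked z-vector (z_x, z_y) is
//   [[ a R^2 + R,  c R^2 ],
//    [ c R^2,      b R^2 + R ]]
// with a = n_x s2b / p, b = n_y (alpha^2 s2b + s2g) / p,
// c = sqrt(n_x n_y) alpha s2b / p. R and R^2 share eigenvectors, so after
// rotating the data (wx = U' z_x, wy = U' z_y) the density factorizes into
// one bivariate normal per eigencomponent with covariance
//   [[ a d^2 + d, c d^2 ], [ c d^2, b d^2 + d ]].
// This makes each likelihood evaluation O(p) after a one-off O(m^3)
// eigendecomposition per block, which is what keeps the delete-one-block
// jackknife affordable.
//
// The 2x2 determinants are accumulated multiplicatively and their log taken
// only when the running product approaches the double range (or at a block
// boundary); log() is the kernel's dominant cost otherwise.
//
// d, wx, wy: concatenated eigenvalues and rotated data over all blocks;
// block: 0-based block index per component, non-decreasing;
// nblocks: number of blocks.
// Returns the log-likelihood contribution of each block.
// [[Rcpp::export(name = ".cl_block_loglik")]]
NumericVector cl_block_loglik(NumericVector d, NumericVector wx,
                              NumericVector wy, IntegerVector block,
                              int nblocks, double a, double b, double c) {
  const double LOG2PI = 1.8378770664093454836;
  NumericVector out(nblocks);
  R_xlen_t n = d.size();
  int cur = n > 0 ? block[0] : 0;
  double det_prod = 1.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (block[i] != cur) {
      out[cur] -= 0.5 * std::log(det_prod);
      det_prod = 1.0;
      cur = block[i];
    }
    double di = d[i], d2 = di * di;
    double v11 = a * d2 + di;
    double v22 = b * d2 + di;
    double v12 = c * d2;
    double det = v11 * v22 - v12 * v12;
    if (det <= 0.0 || v11 <= 0.0) {
      out[block[i]] = R_NegInf;
      det_prod = 1.0;
      continue;
    }
    double x = wx[i], y = wy[i];
    double quad = (v22 * x * x - 2.0 * v12 * x * y + v11 * y * y) / det;
    out[cur] += -LOG2PI - 0.5 * quad;
    det_prod *= det;
    if (det_prod > 1e280 || det_prod < 1e-280) {
      out[cur] -= 0.5 * std::log(det_prod);
      det_prod = 1.0;
    }
  }
  if (n > 0) out[cur] -= 0.5 * std::log(det_prod);
  return out;
}
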
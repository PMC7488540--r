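#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for one weighted-lasso row:
//   min_b (1/(2D)) * sum_j w2[j] * (x[j] - sum_k A(j,k) b[k])^2 + penalty * sum_k |b[k]|
// with an optional nonnegativity clamp on b. w2 holds squared weights.
// Covariance form: G = (1/D) A' W2 A and c = (1/D) A' W2 x are precomputed
// per row, so each coordinate update is O(K). Exact soft-threshold updates.
static void cd_row(const std::vector<double>& G, const std::vector<double>& c,
                   double penalty, bool nonneg, double* b, int K,
                   double tol, int max_sweeps) {
  // gb[k] = (G b)[k], maintained incrementally
  std::vector<double> gb(K, 0.0);
  for (int k = 0; k < K; ++k)
    if (b[k] != 0.0)
      for (int l = 0; l < K; ++l) gb[l] += G[l + k * K] * b[k];
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = G[k + k * K];
      double bk;
      if (s <= 0.0) {                 // no weighted support for this coordinate
        bk = 0.0;
      } else {
        double rho = c[k] - gb[k] + s * b[k];
        if (rho > penalty)       bk = (rho - penalty) / s;
        else if (rho < -penalty) bk = (rho + penalty) / s;
        else                     bk = 0.0;
        if (nonneg && bk < 0.0) bk = 0.0;
      }
      double d = bk - b[k];
      if (d != 0.0) {
        for (int l = 0; l < K; ++l) gb[l] += G[l + k * K] * d;
        b[k] = bk;
        double ad = std::abs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) break;
  }
}

// Update every row of B, where row i of B solves the weighted lasso against
// row i of X / W2 with design A (n x K). Shapes: X, W2 are m x n; B is m x K.
// [[Rcpp::export(name = ".cdUpdateMatrix")]]
NumericMatrix cd_update_matrix(NumericMatrix X, NumericMatrix W2, NumericMatrix A,
                               NumericMatrix B, double penalty, double D,
                               bool nonneg, double tol = 1e-8, int max_sweeps = 1000) {
  int m = X.nrow(), n = X.ncol(), K = A.ncol();
  if (W2.nrow() != m || W2.ncol() != n || A.nrow() != n || B.nrow() != m || B.ncol() != K)
    stop("shape mismatch in coordinate-descent update");
  NumericMatrix out = clone(B);
  std::vector<double> G(K * K), c(K), b(K), wa(n);
  for (int i = 0; i < m; ++i) {
    bool any_w = false;
    for (int j = 0; j < n; ++j) if (W2(i, j) > 0.0) { any_w = true; break; }
    if (!any_w) {                     // all-zero weight row: loading undefined, use 0
      for (int k = 0; k < K; ++k) out(i, k) = 0.0;
      continue;
    }
    // G = (1/D) A' diag(w2_i) A ; c = (1/D) A' diag(w2_i) x_i
    for (int k = 0; k < K; ++k) {
      double ck = 0.0;
      for (int j = 0; j < n; ++j) {
        wa[j] = W2(i, j) * A(j, k);
        ck += wa[j] * X(i, j);
      }
      c[k] = ck / D;
      for (int l = k; l < K; ++l) {
        double g = 0.0;
        for (int j = 0; j < n; ++j) g += wa[j] * A(j, l);
        G[l + k * K] = G[k + l * K] = g / D;
      }
    }
    for (int k = 0; k < K; ++k) b[k] = out(i, k);
    cd_row(G, c, penalty, nonneg, b.data(), K, tol, max_sweeps);
    for (int k = 0; k < K; ++k) out(i, k) = b[k];
  }
  return out;
}
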
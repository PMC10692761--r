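#include <Rcpp.h>
using namespace Rcpp;

// Order-preserving residue correspondence between two C-alpha coordinate
// sets, by dynamic programming maximizing the sum of pair weights
// w_ij = 1 / (1 + (d_ij / r0)^2) with zero gap penalty. Returns 1-based
// index pairs, strictly increasing in both components. Tie-break order:
// diagonal (match) > up > left, so the traceback is deterministic.
// [[Rcpp::export]]
IntegerMatrix dp_correspondence(NumericMatrix A, NumericMatrix B, double r0) {
  const int n = A.nrow(), m = B.nrow();
  std::vector<double> F((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> bt((n + 1) * (m + 1), 0);  // 1=diag 2=up 3=left
  const double inv_r02 = 1.0 / (r0 * r0);
  for (int i = 1; i <= n; ++i) {
    const double ax = A(i - 1, 0), ay = A(i - 1, 1), az = A(i - 1, 2);
    for (int j = 1; j <= m; ++j) {
      const double dx = ax - B(j - 1, 0), dy = ay - B(j - 1, 1),
                   dz = az - B(j - 1, 2);
      const double w = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) * inv_r02);
      const double diag = F[(i - 1) * (m + 1) + (j - 1)] + w;
      const double up = F[(i - 1) * (m + 1) + j];
      const double left = F[i * (m + 1) + (j - 1)];
      double best = diag;
      unsigned char move = 1;
      if (up > best) { best = up; move = 2; }
      if (left > best) { best = left; move = 3; }
      F[i * (m + 1) + j] = best;
      bt[i * (m + 1) + j] = move;
    }
  }
  std::vector<int> ia, ib;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    const unsigned char move = bt[i * (m + 1) + j];
    if (move == 1) {
      ia.push_back(i);
      ib.push_back(j);
      --i; --j;
    } else if (move == 2) {
      --i;
    } else {
      --j;
    }
  }
  const int k = (int)ia.size();
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(t, 0) = ia[k - 1 - t];
    out(t, 1) = ib[k - 1 - t];
  }
  return out;
}
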
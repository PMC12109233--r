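#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Dynamic time warping with unit steps {(1,1),(0,1),(1,0)}, both endpoints
// constrained. Columns of A (bins x n) and B (bins x m) are frames; for the
// cosine metric the caller passes unit-normalised columns and the local
// distance is 1 - <a,b>; for euclidean it is the L2 distance. Two rolling
// cost rows plus a byte traceback matrix keep memory at n*m bytes.

// [[Rcpp::export]]
List dtw_core(NumericMatrix A, NumericMatrix B, int metric_code) {
  const int bins = A.nrow();
  const R_xlen_t n = A.ncol(), m = B.ncol();
  if (B.nrow() != bins) stop("bin count mismatch");
  if (n < 1 || m < 1) stop("empty feature matrix");
  if ((double)n * (double)m > 2147483647.0)
    stop("feature matrices too long for traceback storage");

  RawVector tb((R_xlen_t)(n * m)); // 1 = diag, 2 = left (j-1), 3 = up (i-1)
  std::vector<double> prev(m), cur(m);
  const double *a = REAL(A), *b = REAL(B);

  for (R_xlen_t i = 0; i < n; ++i) {
    const double *ai = a + (R_xlen_t)bins * i;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double *bj = b + (R_xlen_t)bins * j;
      double d;
      if (metric_code == 0) {           // cosine on unit vectors
        double dot = 0.0;
        for (int k = 0; k < bins; ++k) dot += ai[k] * bj[k];
        d = 1.0 - dot;
        if (d < 0.0) d = 0.0;
      } else {                          // euclidean
        double ss = 0.0;
        for (int k = 0; k < bins; ++k) {
          double diff = ai[k] - bj[k];
          ss += diff * diff;
        }
        d = std::sqrt(ss);
      }
      unsigned char step;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0; step = 1;
      } else if (i == 0) {
        best = cur[j - 1]; step = 2;
      } else if (j == 0) {
        best = prev[0]; step = 3;
      } else {
        best = prev[j - 1]; step = 1;   // ties prefer the diagonal
        if (prev[j] < best) { best = prev[j]; step = 3; }
        if (cur[j - 1] < best) { best = cur[j - 1]; step = 2; }
      }
      cur[j] = d + best;
      tb[i * m + j] = step;
    }
    std::swap(prev, cur);
  }
  double total = prev[m - 1];

  // trace back from (n-1, m-1)
  std::vector<int> pi, pj;
  R_xlen_t i = n - 1, j = m - 1;
  while (true) {
    pi.push_back((int)(i + 1));
    pj.push_back((int)(j + 1));
    if (i == 0 && j == 0) break;
    unsigned char s = tb[i * m + j];
    if (s == 1) { --i; --j; }
    else if (s == 2) { --j; }
    else { --i; }
  }
  const R_xlen_t L = (R_xlen_t)pi.size();
  IntegerMatrix path(L, 2);
  for (R_xlen_t k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["path"] = path, _["cost"] = total);
}
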
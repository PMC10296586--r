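// Offset-tolerant dissimilarity between stimulation responses:
// d = 1 - max over integer bin lags |l| <= max_lag of the Pearson correlation
// between the two unit x time matrices flattened over their overlapping
// window at shift l.  Zero-variance windows contribute correlation 0 unless
// the two windows are elementwise identical (then 1), so d(r, r) = 0 and a
// constant record is maximally distant from everything else.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double lag_cor(const NumericMatrix& A, const NumericMatrix& B, int lag) {
  const int nu = A.nrow(), nb = A.ncol();
  // compare A at bins [a0, a0+len) with B at bins [b0, b0+len)
  const int a0 = lag > 0 ? lag : 0;
  const int b0 = lag < 0 ? -lag : 0;
  const int len = nb - std::abs(lag);
  if (len < 2) return 0.0;

  const double n = (double)nu * len;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  bool ident = true;
  for (int j = 0; j < len; ++j) {
    for (int i = 0; i < nu; ++i) {
      const double x = A(i, a0 + j), y = B(i, b0 + j);
      sa += x; sb += y; saa += x * x; sbb += y * y; sab += x * y;
      if (x != y) ident = false;
    }
  }
  const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return ident ? 1.0 : 0.0;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// [[Rcpp::export]]
double cpp_diss_pair(NumericMatrix A, NumericMatrix B, int max_lag) {
  double best = -1.0;
  for (int l = -max_lag; l <= max_lag; ++l) {
    const double r = lag_cor(A, B, l);
    if (r > best) best = r;
  }
  double d = 1.0 - best;
  if (d < 0) d = 0;
  if (d > 2) d = 2;
  return d;
}

// [[Rcpp::export]]
NumericMatrix cpp_diss_matrix(List records, int max_lag) {
  const int n = records.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix A = records[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix B = records[j];
      const double d = cpp_diss_pair(A, B, max_lag);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
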
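#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and a fully
// deterministic traceback. `a` and `b` are 1-based integer encodings of the
// two sequences into the row/column space of `score`, `gap` is the (non
// positive) per-gap score. Tie-breaking: among equal-scoring end cells the
// smallest row, then smallest column wins; during traceback the move
// preference is diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export(name = ".sw_local")]]
List sw_local(IntegerVector a, IntegerVector b, NumericMatrix score,
              double gap) {
  const int m = a.size(), n = b.size();
  NumericMatrix H(m + 1, n + 1);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = score(a[i - 1] - 1, b[j - 1] - 1);
      double h = H(i - 1, j - 1) + s;
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best) {  // strict: keeps smallest row, then smallest column
        best = h;
        bi = i;
        bj = j;
      }
    }
  }
  std::vector<int> pa, pb;
  int i = bi, j = bj;
  const double eps = 1e-9;
  while (i > 0 && j > 0 && H(i, j) > eps) {
    double s = score(a[i - 1] - 1, b[j - 1] - 1);
    if (std::abs(H(i, j) - (H(i - 1, j - 1) + s)) < eps) {
      pa.push_back(i); pb.push_back(j); --i; --j;
    } else if (std::abs(H(i, j) - (H(i - 1, j) + gap)) < eps) {
      pa.push_back(i); pb.push_back(0); --i;
    } else {
      pa.push_back(0); pb.push_back(j); --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_idx"] = IntegerVector(pb.begin(), pb.end()));
}
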
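#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// over the N - m templates, B counts pairs i < j whose length-m vectors are
// within r in Chebyshev distance, A the subset also matching at index m.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}

// Recurrence statistics on the upper triangle of the thresholded distance
// matrix of the (dim, delay) time-delay embedding, Euclidean norm,
// excluding the Theiler band |i-j| <= theiler. Diagonal line structures
// are accumulated per offset.
// [[Rcpp::export]]
List rqa_stats_cpp(NumericVector x, int dim, int delay, double radius,
                   int theiler, int lmin) {
  int n = x.size();
  int ne = n - (dim - 1) * delay;
  double r2 = radius * radius;
  double rec = 0.0, npairs = 0.0;
  double pts_on_lines = 0.0, nlines = 0.0, sumlen = 0.0;
  int maxlen = 0;
  for (int d = theiler + 1; d <= ne - 1; ++d) {
    int len = ne - d;  // points on this diagonal
    npairs += len;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      double dist2 = 0.0;
      for (int k = 0; k < dim; ++k) {
        double diff = x[i + k * delay] - x[i + d + k * delay];
        dist2 += diff * diff;
        if (dist2 > r2) break;
      }
      bool hit = dist2 <= r2;
      if (hit) { rec += 1.0; ++run; }
      if ((!hit || i == len - 1) && run > 0) {
        if (run >= lmin) {
          pts_on_lines += run;
          nlines += 1.0;
          sumlen += run;
          if (run > maxlen) maxlen = run;
        }
        run = 0;
      }
    }
  }
  return List::create(_["rec"] = rec, _["npairs"] = npairs,
                      _["pts_on_lines"] = pts_on_lines,
                      _["nlines"] = nlines, _["sumlen"] = sumlen,
                      _["maxlen"] = maxlen, _["ne"] = ne);
}
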
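#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance).
// Counts unordered pairs i < j, i,j in 0..(N-m-1), matching at length m
// (B) and at length m+1 (A); self-matches excluded by construction.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  int n = x.size();
  int nt = n - m; // number of templates that also have an (m+1)th point
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > tol) break;
      }
      if (d <= tol) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Cross-template counts: templates from x matched against y (ordered
// pairs over all i, j; no self-match concept for distinct series).
// [[Rcpp::export]]
NumericVector cross_sampen_counts(NumericVector x, NumericVector y,
                                  int m, double tol) {
  int n = x.size();
  int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - y[j + k]);
        if (dk > d) d = dk;
        if (d > tol) break;
      }
      if (d <= tol) {
        B += 1.0;
        if (std::fabs(x[i + m] - y[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Nearest neighbour of each row of an embedding matrix under Euclidean
// distance, excluding neighbours within `theiler` rows (temporal
// decorrelation window). Returns 1-based indices and distances; index 0
// when no admissible neighbour exists.
// [[Rcpp::export]]
List nearest_neighbors(NumericMatrix emb, int theiler) {
  int n = emb.nrow(), d = emb.ncol();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double dk = emb(i, k) - emb(j, k);
        s += dk * dk;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = (bj >= 0) ? std::sqrt(best) : NA_REAL;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
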
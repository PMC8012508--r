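#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy (Pincus): Phi^m(r) - Phi^{m+1}(r), Chebyshev distance,
// self-matches included. Counts for m and m+1 are accumulated in one pass
// over template pairs; equals the O(N^2) textbook double loop exactly.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (r <= 0) stop("r must be > 0");
  if (n < m + 2) stop("series too short for embedding dimension m");

  // Phi^m over N - m + 1 templates
  double phi_m = 0.0, phi_m1 = 0.0;
  {
    int nt = n - m + 1;
    std::vector<int> cnt(nt, 0);
    for (int i = 0; i < nt; ++i) {
      cnt[i]++;  // self-match
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) d = a;
          if (d > r) break;
        }
        if (d <= r) { cnt[i]++; cnt[j]++; }
      }
    }
    for (int i = 0; i < nt; ++i)
      phi_m += std::log((double)cnt[i] / nt);
    phi_m /= nt;
  }
  {
    int m1 = m + 1;
    int nt = n - m1 + 1;
    std::vector<int> cnt(nt, 0);
    for (int i = 0; i < nt; ++i) {
      cnt[i]++;
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < m1; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) d = a;
          if (d > r) break;
        }
        if (d <= r) { cnt[i]++; cnt[j]++; }
      }
    }
    for (int i = 0; i < nt; ++i)
      phi_m1 += std::log((double)cnt[i] / nt);
    phi_m1 /= nt;
  }
  return phi_m - phi_m1;
}

// Sample entropy: -log(A/B) with A, B the m+1 and m template-match pair
// counts over the N - m templates, self-matches excluded (Richman & Moorman).
// Returns NA when A or B is zero.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (r <= 0) stop("r must be > 0");
  if (n < m + 2) stop("series too short for embedding dimension m");
  int nt = n - m;  // templates for which an (m+1)-extension exists
  long long A = 0, B = 0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        B++;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A++;
      }
    }
  }
  if (B == 0) return NA_REAL;
  if (A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}
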
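#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) ancestor-tracing
// algorithm. sire/dam are 1-based ids, 0 = unknown; parents must precede
// offspring. a_ii = sum_j L_j^2 D_j over the ancestors j of i, with D_j the
// Mendelian-sampling variance of j; F_i = a_ii - 1.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(const IntegerVector& sire,
                             const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  std::vector<bool> inq(n, false);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > 0 && d > 0)
      D[i] = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    else if (s > 0)
      D[i] = 0.75 - 0.25 * F[s - 1];
    else if (d > 0)
      D[i] = 0.75 - 0.25 * F[d - 1];
    else
      D[i] = 1.0;

    if (s == 0 || d == 0) { F[i] = 0.0; continue; }

    // trace ancestors of i in decreasing id order
    std::priority_queue<int> q;
    double aii = 0.0;
    L[i] = 1.0; q.push(i); inq[i] = true;
    while (!q.empty()) {
      const int j = q.top(); q.pop(); inq[j] = false;
      const int js = sire[j], jd = dam[j];
      if (js > 0) {
        L[js - 1] += 0.5 * L[j];
        if (!inq[js - 1]) { q.push(js - 1); inq[js - 1] = true; }
      }
      if (jd > 0) {
        L[jd - 1] += 0.5 * L[j];
        if (!inq[jd - 1]) { q.push(jd - 1); inq[jd - 1] = true; }
      }
      aii += L[j] * L[j] * D[j];
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
    // D[i] was provisional only if i's parents' F were already final, which
    // holds because parents precede offspring.
  }
  return F;
}

// Numerator relationship matrix by the tabular method. Dense; intended for
// moderate pedigrees (oracles, genotyped-ancestor subsets).
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(const IntegerVector& sire,
                            const IntegerVector& dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = A(j, i) = a;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A(s, d);
    A(i, i) = aii;
  }
  return A;
}
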
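#include <Rcpp.h>
using namespace Rcpp;

// Meiosis under a Haldane model: crossover count per chromosome is
// Poisson(length in Morgans), crossover positions uniform, no interference.
// Positions are cM within chromosome; chromosomes delimited by [start, end).
// Recurrent mutation (applied to the finished gamete when mutRate > 0):
// Poisson(nLoci * mutRate) mutations at uniform loci; a mutated locus moves
// to one of its other alleles uniformly (kAlleles per locus; 2 = flip).
// All randomness comes from R's RNG, so set.seed() governs results.

static void drop_one(const IntegerMatrix& hap, const int parent,
                     IntegerMatrix& out, const int col,
                     const NumericVector& pos,
                     const IntegerVector& chromStart,
                     const IntegerVector& chromEnd,
                     const NumericVector& chromLen,
                     const double mutRate,
                     const IntegerVector& kAlleles,
                     std::vector<double>& cx) {
  const int nChrom = chromStart.size();
  const int c0 = 2 * parent, c1 = 2 * parent + 1;
  const int nLoci = hap.nrow();
  for (int c = 0; c < nChrom; ++c) {
    int ncx = (int) R::rpois(chromLen[c] / 100.0);
    cx.resize(ncx);
    for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * chromLen[c];
    std::sort(cx.begin(), cx.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int k = 0;
    for (int l = chromStart[c]; l < chromEnd[c]; ++l) {
      while (k < ncx && cx[k] < pos[l]) { cur = 1 - cur; ++k; }
      out(l, col) = hap(l, cur == 0 ? c0 : c1);
    }
  }
  if (mutRate > 0) {
    int nmut = (int) R::rpois(mutRate * nLoci);
    for (int j = 0; j < nmut; ++j) {
      int l = (int) (unif_rand() * nLoci);
      if (l >= nLoci) l = nLoci - 1;
      const int k = kAlleles[l];
      const int step = 1 + (int) (unif_rand() * (k - 1));
      out(l, col) = 1 + (out(l, col) - 1 + step) % k;
    }
  }
}

// One gamete per entry of `parent` (0-based animal index owning columns
// 2k and 2k+1 of `hap`).
// [[Rcpp::export]]
IntegerMatrix cpp_drop_gametes(const IntegerMatrix& hap,
                               const IntegerVector& parent,
                               const NumericVector& pos,
                               const IntegerVector& chromStart,
                               const IntegerVector& chromEnd,
                               const NumericVector& chromLen,
                               const double mutRate,
                               const IntegerVector& kAlleles) {
  const int nGam = parent.size();
  IntegerMatrix out(hap.nrow(), nGam);
  std::vector<double> cx;
  for (int g = 0; g < nGam; ++g)
    drop_one(hap, parent[g], out, g, pos, chromStart, chromEnd, chromLen,
             mutRate, kAlleles, cx);
  return out;
}

// A whole offspring generation in one allocation: offspring j receives its
// paternal gamete (from sire[j]) in column 2j and its maternal gamete (from
// dam[j]) in column 2j+1. Paternal gametes for the whole cohort are drawn
// first, then maternal ones, matching two cpp_drop_gametes() calls.
// [[Rcpp::export]]
IntegerMatrix cpp_next_generation(const IntegerMatrix& hap,
                                  const IntegerVector& sire,
                                  const IntegerVector& dam,
                                  const NumericVector& pos,
                                  const IntegerVector& chromStart,
                                  const IntegerVector& chromEnd,
                                  const NumericVector& chromLen,
                                  const double mutRate,
                                  const IntegerVector& kAlleles) {
  const int n = sire.size();
  IntegerMatrix out(hap.nrow(), 2 * n);
  std::vector<double> cx;
  for (int j = 0; j < n; ++j)
    drop_one(hap, sire[j], out, 2 * j, pos, chromStart, chromEnd, chromLen,
             mutRate, kAlleles, cx);
  for (int j = 0; j < n; ++j)
    drop_one(hap, dam[j], out, 2 * j + 1, pos, chromStart, chromEnd,
             chromLen, mutRate, kAlleles, cx);
  return out;
}
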
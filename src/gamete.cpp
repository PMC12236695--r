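// Recombination kernel of the forward simulator. A haplotype is a pair of
// vectors (ends, anc): segment i covers the half-open genetic interval
// [ends[i-1], ends[i]) in Morgans, with ends[0] implicitly preceded by 0 and
// the final end equal to the chromosome length; anc is the parent-of-origin
// label of the segment. Crossover positions are drawn from the R RNG so a
// set.seed() in R fixes the whole simulation.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// One meiosis: Poisson(L) crossovers at uniform positions, random starting
// haplotype, alternating at each crossover. Returns the gamete haplotype.
// [[Rcpp::export]]
List cpp_gamete(NumericVector ends1, IntegerVector anc1,
                NumericVector ends2, IntegerVector anc2, double L) {
  int nx = (int) R::rpois(L);
  int src = (unif_rand() < 0.5) ? 0 : 1;
  if (nx == 0) {
    if (src == 0) return List::create(_["ends"] = ends1, _["anc"] = anc1);
    return List::create(_["ends"] = ends2, _["anc"] = anc2);
  }
  std::vector<double> xo(nx);
  for (int i = 0; i < nx; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());

  std::vector<double> out_ends;
  std::vector<int> out_anc;
  out_ends.reserve(ends1.size() + ends2.size() + nx);
  out_anc.reserve(ends1.size() + ends2.size() + nx);

  int i1 = 0, i2 = 0, k = 0;
  double pos = 0.0;
  while (pos < L) {
    // advance segment pointers past the current position
    while (i1 < ends1.size() - 1 && ends1[i1] <= pos) ++i1;
    while (i2 < ends2.size() - 1 && ends2[i2] <= pos) ++i2;
    double b_src = (src == 0) ? ends1[i1] : ends2[i2];
    double b_xo = (k < nx) ? xo[k] : L + 1.0;
    double nb = std::min(b_src, std::min(b_xo, L));
    int a = (src == 0) ? anc1[i1] : anc2[i2];
    if (nb > pos) {
      if (!out_anc.empty() && out_anc.back() == a)
        out_ends.back() = nb;           // merge adjacent equal-label tracts
      else {
        out_ends.push_back(nb);
        out_anc.push_back(a);
      }
      pos = nb;
    }
    if (k < nx && b_xo <= pos) {        // crossover: switch source haplotype
      ++k;
      src = 1 - src;
    }
  }
  out_ends.back() = L;                  // guard against float round-off
  return List::create(_["ends"] = NumericVector(out_ends.begin(), out_ends.end()),
                      _["anc"] = IntegerVector(out_anc.begin(), out_anc.end()));
}
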
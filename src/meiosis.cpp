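#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gamete formation for one chromosome under the Haldane model: crossover
// count Poisson on the genetic length, positions uniform, no interference.
// haps: markers x haplotypes (individual i occupies columns 2i-1, 2i;
// 1-based). parents: 1-based individual index per gamete. cm: marker
// positions in centimorgans. Uses R's RNG, so results are reproducible
// from set.seed().
// [[Rcpp::export]]
IntegerMatrix make_gametes(const IntegerMatrix& haps,
                           const IntegerVector& parents,
                           const NumericVector& cm) {
  const int M = haps.nrow();
  const int G = parents.size();
  if (cm.size() != M) stop("cm length must equal marker count");
  IntegerMatrix out(M, G);
  const double L = (cm[M - 1] - cm[0]) / 100.0;  // morgans
  std::vector<double> xo;
  for (int g = 0; g < G; ++g) {
    const int ind = parents[g];
    if (ind < 1 || 2 * ind > haps.ncol()) stop("parent index out of range");
    const int colA = 2 * ind - 2, colB = 2 * ind - 1;
    int k = (L > 0) ? (int) R::rpois(L) : 0;
    xo.resize(k);
    for (int i = 0; i < k; ++i) xo[i] = cm[0] + unif_rand() * (cm[M - 1] - cm[0]);
    std::sort(xo.begin(), xo.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    const int* hA = &haps(0, colA);
    const int* hB = &haps(0, colB);
    int* o = &out(0, g);
    const double* cmp = &cm[0];
    int m = 0;
    // copy whole segments between successive crossover points
    for (int xi = 0; xi <= k; ++xi) {
      const double stop_at = (xi < k) ? xo[xi] : R_PosInf;
      const int* src = cur ? hB : hA;
      while (m < M && cmp[m] < stop_at) { o[m] = src[m]; ++m; }
      cur ^= 1;
    }
  }
  return out;
}
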
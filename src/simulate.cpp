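#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequential conditional-sampling haplotype generator (Li & Stephens style
// approximation to the coalescent with recombination). Haplotype k is an
// imperfect mosaic of haplotypes 0..k-1: segment sources switch along the
// map as a Poisson process of rate 4*Ne*r/k per base pair, and each site is
// "born" on one haplotype (birth[j] = 0-based haplotype index), after which
// it spreads to descendants through copying. Haplotype 0 is all-ancestral
// apart from its own births. Uses R's RNG, so runs are reproducible under
// set.seed().
// [[Rcpp::export]]
RawMatrix cpp_mosaic_panel(int nHap, NumericVector pos, IntegerVector birth,
                           double Ne, double recRate) {
  const int M = pos.size();
  if ((int)birth.size() != M) stop("birth vector length mismatch");
  RawMatrix H(nHap, M);

  // cumulative physical distance used as the switch clock
  std::vector<double> G(M, 0.0);
  for (int j = 1; j < M; ++j) G[j] = G[j - 1] + (pos[j] - pos[j - 1]);

  std::vector<std::vector<int> > births(nHap);
  for (int j = 0; j < M; ++j) {
    if (birth[j] < 0 || birth[j] >= nHap) stop("birth index out of range");
    births[birth[j]].push_back(j);
  }

  for (int j = 0; j < M; ++j) H(0, j) = 0;
  for (size_t i = 0; i < births[0].size(); ++i) H(0, births[0][i]) = 1;

  for (int k = 1; k < nHap; ++k) {
    const double rate = 4.0 * Ne * recRate / (double)k;
    int src = (int)(R::unif_rand() * k);
    if (src >= k) src = k - 1;
    double nextSwitch = G[0] + R::exp_rand() / rate;
    for (int j = 0; j < M; ++j) {
      if (G[j] >= nextSwitch) {
        src = (int)(R::unif_rand() * k);
        if (src >= k) src = k - 1;
        nextSwitch = G[j] + R::exp_rand() / rate;
      }
      H(k, j) = H(src, j);
    }
    for (size_t i = 0; i < births[k].size(); ++i) H(k, births[k][i]) = 1;
  }
  return H;
}
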
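#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int allele_at(const RawMatrix &H, int row, int col) {
  return (int)H[(R_xlen_t)col * H.nrow() + row];
}

// Per-interval switch probability of the copying chain:
//   rho_m = 1 - exp(-4 * Ne * g / S),  g = genetic gap in Morgans,
// floored at minRho so the chain never freezes between co-sited markers.
static inline double rho_of(double cmGap, int S, double Ne, double minRho) {
  double r = 1.0 - std::exp(-4.0 * Ne * (cmGap / 100.0) / (double)S);
  return (r < minRho) ? minRho : r;
}

// Does selected state s (0-based position within `states`) carry the
// alternate allele in record `rec`?  Records follow the binary reference
// encoding: sparse = sorted carrier indices, bitset = one bit per haplotype.
static inline bool carries_alt(SEXP rec, int tag, int hap) {
  if (tag == 0) {
    IntegerVector cv(rec);
    return std::binary_search(cv.begin(), cv.end(), hap);
  }
  RawVector bv(rec);
  return (bv[hap >> 3] >> (hap & 7)) & 1;
}

// Full per-target imputation: scaled forward-backward over the selected
// states at typed markers, posterior thresholding (threshold 1/S, the
// argmax state always retained), renormalised linear interpolation at
// untyped markers, and the delayed lazy path for rare variants.
//
// leftFlank[u] (0-based):  -1  -> before first typed marker (use marker 0),
//                          MT-1 -> after last typed marker,
//                          else interval [leftFlank, leftFlank+1] with
//                          weight[u] in [0,1] (0 = at the left flank).
// [[Rcpp::export]]
List cpp_impute_target(RawMatrix refTyped, IntegerVector states,
                       IntegerVector tgt, NumericVector cmTyped,
                       double Ne, double minRho,
                       double eMatch, double eMismatch,
                       bool sparsify,
                       List records, IntegerVector recTag,
                       IntegerVector leftFlank, NumericVector weight,
                       LogicalVector rareFlag, bool lazy,
                       bool returnP) {
  const int S = states.size();
  const int MT = cmTyped.size();
  const int MU = records.size();
  if (S < 1) stop("empty copying-state list");
  if ((int)tgt.size() != MT) stop("target length does not match typed markers");

  // emission table: match/mismatch against each selected state's allele
  std::vector<double> emit((size_t)S * MT);
  for (int m = 0; m < MT; ++m)
    for (int s = 0; s < S; ++s)
      emit[(size_t)m * S + s] =
        (allele_at(refTyped, states[s], m) == tgt[m]) ? eMatch : eMismatch;

  std::vector<double> fwd((size_t)S * MT), bwd((size_t)S * MT);
  // forward, rescaled to sum 1 per marker
  {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) { fwd[s] = emit[s] / S; tot += fwd[s]; }
    for (int s = 0; s < S; ++s) fwd[s] /= tot;
  }
  for (int m = 1; m < MT; ++m) {
    const double rho = rho_of(cmTyped[m] - cmTyped[m - 1], S, Ne, minRho);
    const double stay = 1.0 - rho, jump = rho / S;
    double tot = 0.0;
    const double *fp = &fwd[(size_t)(m - 1) * S];
    double *fc = &fwd[(size_t)m * S];
    const double *em = &emit[(size_t)m * S];
    for (int s = 0; s < S; ++s) {
      fc[s] = em[s] * (stay * fp[s] + jump);
      tot += fc[s];
    }
    for (int s = 0; s < S; ++s) fc[s] /= tot;
  }
  // backward, rescaled per marker (any per-marker scale is cancelled when
  // posteriors are normalised)
  {
    double *bl = &bwd[(size_t)(MT - 1) * S];
    for (int s = 0; s < S; ++s) bl[s] = 1.0 / S;
  }
  for (int m = MT - 2; m >= 0; --m) {
    const double rho = rho_of(cmTyped[m + 1] - cmTyped[m], S, Ne, minRho);
    const double stay = 1.0 - rho, jump = rho / S;
    const double *bn = &bwd[(size_t)(m + 1) * S];
    const double *em = &emit[(size_t)(m + 1) * S];
    double *bc = &bwd[(size_t)m * S];
    double acc = 0.0;
    for (int s = 0; s < S; ++s) acc += em[s] * bn[s];
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      bc[s] = stay * em[s] * bn[s] + jump * acc;
      tot += bc[s];
    }
    for (int s = 0; s < S; ++s) bc[s] /= tot;
  }
  // posteriors
  std::vector<double> P((size_t)S * MT);
  for (int m = 0; m < MT; ++m) {
    double tot = 0.0;
    double *pm = &P[(size_t)m * S];
    const double *fm = &fwd[(size_t)m * S], *bm = &bwd[(size_t)m * S];
    for (int s = 0; s < S; ++s) { pm[s] = fm[s] * bm[s]; tot += pm[s]; }
    for (int s = 0; s < S; ++s) pm[s] /= tot;
  }

  // dosages at typed markers: full posterior mass on alt carriers
  NumericVector dosTyped(MT);
  for (int m = 0; m < MT; ++m) {
    const double *pm = &P[(size_t)m * S];
    double dsum = 0.0;
    for (int s = 0; s < S; ++s)
      if (allele_at(refTyped, states[s], m) == 1) dsum += pm[s];
    dosTyped[m] = dsum;
  }

  // per-typed-marker stored mask (posterior > 1/S; argmax kept)
  const double thr = 1.0 / (double)S;
  std::vector<char> keep((size_t)S * MT, sparsify ? 0 : 1);
  if (sparsify) {
    for (int m = 0; m < MT; ++m) {
      const double *pm = &P[(size_t)m * S];
      int best = 0;
      for (int s = 0; s < S; ++s) {
        if (pm[s] > thr) keep[(size_t)m * S + s] = 1;
        if (pm[s] > pm[best]) best = s;
      }
      keep[(size_t)m * S + best] = 1;
    }
  }

  // interpolation over untyped markers, caching per-interval renormalised
  // flank posteriors for the stored union
  NumericVector dosUntyped(MU);
  int cachedL = -2;
  std::vector<int> storedIdx;
  std::vector<double> pl, pr;
  for (int u = 0; u < MU; ++u) {
    int lf = leftFlank[u];
    int ml = (lf < 0) ? 0 : lf;
    int mr = (lf < 0) ? 0 : ((lf >= MT - 1) ? MT - 1 : lf + 1);
    if (lf != cachedL) {
      storedIdx.clear(); pl.clear(); pr.clear();
      double sl = 0.0, sr = 0.0;
      for (int s = 0; s < S; ++s) {
        if (keep[(size_t)ml * S + s] || keep[(size_t)mr * S + s]) {
          storedIdx.push_back(s);
          pl.push_back(P[(size_t)ml * S + s]);
          pr.push_back(P[(size_t)mr * S + s]);
          sl += pl.back(); sr += pr.back();
        }
      }
      for (size_t i = 0; i < pl.size(); ++i) { pl[i] /= sl; pr[i] /= sr; }
      cachedL = lf;
    }
    const int tag = recTag[u];
    SEXP rec = records[u];
    if (lazy && rareFlag[u]) {
      // delayed lazy path: skip interpolation when no stored state carries alt
      bool any = false;
      for (size_t i = 0; i < storedIdx.size() && !any; ++i)
        any = carries_alt(rec, tag, states[storedIdx[i]]);
      if (!any) { dosUntyped[u] = 0.0; continue; }
    }
    const double w = weight[u];
    double dsum = 0.0;
    for (size_t i = 0; i < storedIdx.size(); ++i) {
      if (carries_alt(rec, tag, states[storedIdx[i]]))
        dsum += (1.0 - w) * pl[i] + w * pr[i];
    }
    if (dsum < 0.0) dsum = 0.0;
    if (dsum > 1.0) dsum = 1.0;
    dosUntyped[u] = dsum;
  }

  List out = List::create(_["dosTyped"] = dosTyped,
                          _["dosUntyped"] = dosUntyped);
  if (returnP) {
    NumericMatrix Pm(S, MT);
    std::copy(P.begin(), P.end(), Pm.begin());
    out["P"] = Pm;
  }
  return out;
}
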
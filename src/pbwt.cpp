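#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Core PBWT machinery. Conventions (0-based throughout the C++ layer):
//  - A is the positional prefix array at marker m: haplotype indices in
//    reverse-prefix lexicographic order over markers 0..m.
//  - Y[n] = H[Aprev[n], m] is the PBWT column at m.
//  - U[n]/V[n] are inclusive ranks: counts of 0/1 symbols in Y[0..n], so
//    U[n] + V[n] = n + 1 at every position.
//  - D[n] is the start marker of the maximal reverse-prefix match between
//    A[n-1] and A[n] ending at m; sentinel D[0] = m + 1. The initial state
//    (before any marker) has A = identity and D = 0 with sentinel 0.

// Single-pass update of (A, D) plus rank structures for one marker column.
// Durbin-style counting sort with the divergence recursion.
// [[Rcpp::export]]
List cpp_pbwt_advance(IntegerVector Aprev, IntegerVector Dprev,
                      IntegerVector hcol, int m) {
  const int N = Aprev.size();
  if ((int)hcol.size() != N)
    stop("column length does not match panel size");
  IntegerVector Y(N), U(N), V(N), A(N), D(N);
  std::vector<int> a, b, d, e;
  a.reserve(N); b.reserve(N); d.reserve(N); e.reserve(N);
  int p = m + 1, q = m + 1;
  int u = 0, v = 0;
  for (int n = 0; n < N; ++n) {
    const int y = hcol[Aprev[n]];
    if (y != 0 && y != 1) stop("non-binary allele in column");
    Y[n] = y;
    if (Dprev[n] > p) p = Dprev[n];
    if (Dprev[n] > q) q = Dprev[n];
    if (y == 0) {
      a.push_back(Aprev[n]); d.push_back(p); p = 0; ++u;
    } else {
      b.push_back(Aprev[n]); e.push_back(q); q = 0; ++v;
    }
    U[n] = u; V[n] = v;
  }
  const int c = u;
  for (size_t i = 0; i < a.size(); ++i) { A[i] = a[i]; D[i] = d[i]; }
  for (size_t i = 0; i < b.size(); ++i) {
    A[c + i] = b[i]; D[c + i] = e[i];
  }
  D[0] = m + 1;  // sentinel: no haplotype above rank 0
  return List::create(_["A"] = A, _["Y"] = Y, _["c"] = c,
                      _["U"] = U, _["V"] = V, _["D"] = D);
}

static inline int ref_allele(const RawMatrix &H, int row, int col) {
  return (int)H[(R_xlen_t)col * H.nrow() + row];
}

// Start of the maximal reverse-prefix match (ending at marker m) between the
// target and reference haplotype `hap`, by direct backward scan.
static int match_start_scan(const RawMatrix &refT, const RawMatrix &tgtT,
                            int hap, int t, int m) {
  int start = m + 1;
  for (int k = m; k >= 0; --k) {
    if (ref_allele(refT, hap, k) != ref_allele(tgtT, t, k)) break;
    start = k;
  }
  return start;
}

// Divergence selection (two-pointer expansion around the insertion slot f,
// running match starts maintained as prefix maxima of D). dup/ddn are the
// match starts between the target and A[f-1] / A[f].
static void divergence_pick(const int *A, const int *D, int N, int f,
                            int dup, int ddn, int L, std::vector<int> &out) {
  int i = f - 1, j = f;
  while ((int)out.size() < L && (i >= 0 || j < N)) {
    bool takeUp;
    if (i < 0) takeUp = false;
    else if (j >= N) takeUp = true;
    else takeUp = (dup <= ddn);  // tie goes to the upper side
    if (takeUp) {
      out.push_back(A[i]);
      if (i > 0 && D[i] > dup) dup = D[i];
      --i;
    } else {
      out.push_back(A[j]);
      if (j + 1 < N && D[j + 1] > ddn) ddn = D[j + 1];
      ++j;
    }
  }
}

// Neighbour selection: ceil(L/2) states above the slot, floor(L/2) below,
// clipped at the panel borders (no borrowing across a border). With the
// mismatch guard, a candidate whose allele at the current marker mismatches
// the target is skipped when the opposite side's candidate matches; the
// matching side is extended instead (charged to the skipped side's budget).
static void neighbour_pick(const int *A, int N, int f, int L, bool guard,
                           const RawMatrix *refT, const RawMatrix *tgtT,
                           int t, int m, std::vector<int> &out) {
  int upLeft = (L + 1) / 2, dnLeft = L / 2;
  int i = f - 1, j = f;
  bool sideUp = true;
  while ((int)out.size() < L) {
    const bool upPtr = (i >= 0), dnPtr = (j < N);
    const bool canUp = (upLeft > 0) && upPtr;
    const bool canDn = (dnLeft > 0) && dnPtr;
    if (!canUp && !canDn) break;
    bool up = canUp && (!canDn || sideUp);
    if (guard) {
      const int tm = ref_allele(*tgtT, t, m);
      const bool upMatch = upPtr && ref_allele(*refT, A[i], m) == tm;
      const bool dnMatch = dnPtr && ref_allele(*refT, A[j], m) == tm;
      // shift only needs the opposite pointer in range: the matching side
      // may be extended beyond its own L/2 budget
      if (up && !upMatch && dnMatch) {
        out.push_back(A[j]); ++j; --upLeft; sideUp = true; continue;
      }
      if (!up && !dnMatch && upMatch) {
        out.push_back(A[i]); --i; --dnLeft; sideUp = false; continue;
      }
    }
    if (up) { out.push_back(A[i]); --i; --upLeft; sideUp = false; }
    else    { out.push_back(A[j]); ++j; --dnLeft; sideUp = true; }
  }
}

// One left-to-right pass over the typed markers: PBWT advance, O(1) target
// insertion via the rank structures, and state harvesting at selection
// markers. Returns per-target state lists (with per-state event counts) and
// the per-target insertion-position trace at selection markers.
// method: 0 = neighbour, 1 = divergence.
// [[Rcpp::export]]
List cpp_selection_sweep(RawMatrix refTyped, RawMatrix tgtTyped,
                         IntegerVector selIdx, int L, int method,
                         bool guard) {
  const int N = refTyped.nrow(), MT = refTyped.ncol();
  const int K = tgtTyped.nrow();
  if (tgtTyped.ncol() != MT) stop("panels disagree on typed markers");
  const int nSel = selIdx.size();

  std::vector<int> Aprev(N), A(N), Dprev(N, 0), D(N);
  std::vector<int> a, b, d, e;
  a.reserve(N); b.reserve(N); d.reserve(N); e.reserve(N);
  std::vector<int> U(N), V(N);
  for (int n = 0; n < N; ++n) Aprev[n] = n;
  std::vector<int> f(K, 0);

  std::vector<std::vector<unsigned short> > counts(
      K, std::vector<unsigned short>(N, 0));
  IntegerMatrix fTrace(K, nSel);
  int selPtr = 0;
  std::vector<int> picked;

  for (int m = 0; m < MT; ++m) {
    // advance the column (counting sort + divergence recursion)
    a.clear(); b.clear(); d.clear(); e.clear();
    int p = m + 1, q = m + 1, u = 0, v = 0;
    const Rbyte *hc = &refTyped[(R_xlen_t)m * N];
    for (int n = 0; n < N; ++n) {
      const int y = (int)hc[Aprev[n]];
      if (Dprev[n] > p) p = Dprev[n];
      if (Dprev[n] > q) q = Dprev[n];
      if (y == 0) { a.push_back(Aprev[n]); d.push_back(p); p = 0; ++u; }
      else        { b.push_back(Aprev[n]); e.push_back(q); q = 0; ++v; }
      U[n] = u; V[n] = v;
    }
    const int c = u;
    for (size_t i2 = 0; i2 < a.size(); ++i2) { A[i2] = a[i2]; D[i2] = d[i2]; }
    for (size_t i2 = 0; i2 < b.size(); ++i2) {
      A[c + i2] = b[i2]; D[c + i2] = e[i2];
    }
    D[0] = m + 1;

    // O(1) insertion update for every target
    for (int t = 0; t < K; ++t) {
      const int tm = ref_allele(tgtTyped, t, m);
      const int ft = f[t];
      if (tm == 0) f[t] = (ft == 0) ? 0 : U[ft - 1];
      else         f[t] = c + ((ft == 0) ? 0 : V[ft - 1]);
    }

    if (selPtr < nSel && selIdx[selPtr] == m) {
      for (int t = 0; t < K; ++t) {
        fTrace(t, selPtr) = f[t];
        picked.clear();
        if (method == 1) {
          const int dup = (f[t] > 0)
            ? match_start_scan(refTyped, tgtTyped, A[f[t] - 1], t, m)
            : m + 2;  // border: never preferred over a real neighbour
          const int ddn = (f[t] < N)
            ? match_start_scan(refTyped, tgtTyped, A[f[t]], t, m)
            : m + 2;
          divergence_pick(A.data(), D.data(), N, f[t], dup, ddn, L, picked);
        } else {
          neighbour_pick(A.data(), N, f[t], L, guard,
                         &refTyped, &tgtTyped, t, m, picked);
        }
        for (size_t s = 0; s < picked.size(); ++s) {
          if (counts[t][picked[s]] < 65535) ++counts[t][picked[s]];
        }
      }
      ++selPtr;
    }
    std::swap(Aprev, A);
    std::swap(Dprev, D);
  }

  List states(K), eventCounts(K);
  for (int t = 0; t < K; ++t) {
    std::vector<int> st, ct;
    for (int n = 0; n < N; ++n) {
      if (counts[t][n] > 0) { st.push_back(n); ct.push_back(counts[t][n]); }
    }
    states[t] = IntegerVector(st.begin(), st.end());
    eventCounts[t] = IntegerVector(ct.begin(), ct.end());
  }
  return List::create(_["states"] = states, _["eventCounts"] = eventCounts,
                      _["fTrace"] = fTrace);
}

// Per-column alt-allele counts, optionally over a subset of haplotypes
// (rows, 0-based). Raw matrices have no colSums in base R.
// [[Rcpp::export]]
IntegerVector cpp_alt_counts(RawMatrix H, Nullable<IntegerVector> rows) {
  const int N = H.nrow(), M = H.ncol();
  IntegerVector out(M);
  if (rows.isNull()) {
    for (int j = 0; j < M; ++j) {
      const Rbyte *col = &H[(R_xlen_t)j * N];
      int s = 0;
      for (int i = 0; i < N; ++i) s += col[i];
      out[j] = s;
    }
  } else {
    IntegerVector r(rows);
    for (int j = 0; j < M; ++j) {
      const Rbyte *col = &H[(R_xlen_t)j * N];
      int s = 0;
      for (int i = 0; i < r.size(); ++i) s += col[r[i]];
      out[j] = s;
    }
  }
  return out;
}

// 0/1-only check without allocating logical temporaries (validity of large
// panels must not triple memory use).
// [[Rcpp::export]]
bool cpp_is_binary(RawMatrix H) {
  const R_xlen_t n = (R_xlen_t)H.nrow() * H.ncol();
  for (R_xlen_t i = 0; i < n; ++i)
    if (H[i] > 1) return false;
  return true;
}
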
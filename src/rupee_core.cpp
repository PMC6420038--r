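#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// splitmix64 finalizer: the fixed 64-bit mixing function behind the min-hash
// family, band hashes and seed derivation. Versioned: changing any constant
// invalidates existing indexes (the seed id in the index header guards this).
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int h31(uint64_t x) {
  // top 31 bits -> non-negative R integer
  return (int)(x >> 33);
}

// [[Rcpp::export]]
IntegerVector cpp_minhash(IntegerVector values, IntegerVector counts,
                          int n_hashes, double seed) {
  int m = values.size();
  uint64_t base = (uint64_t)(int64_t)seed;
  IntegerVector out(n_hashes);
  std::vector<uint64_t> hv(m);
  for (int i = 0; i < m; ++i)
    hv[i] = mix64((uint64_t)(uint32_t)values[i] + 0x51ED270B9ULL);
  for (int k = 0; k < n_hashes; ++k) {
    uint64_t sk = mix64(base + 0xA24BAED4963EE407ULL * (uint64_t)(k + 1));
    uint64_t best = UINT64_MAX;
    for (int i = 0; i < m; ++i) {
      uint64_t h = mix64(hv[i] ^ sk);
      int c = counts[i];
      for (int j = 0; j < c; ++j) {
        uint64_t t = (j == 0) ? h : mix64(h + (uint64_t)j);
        if (t < best) best = t;
      }
    }
    out[k] = h31(best);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_band_hashes(IntegerVector sig, int bands, int rows) {
  IntegerVector out(bands);
  for (int b = 0; b < bands; ++b) {
    uint64_t h = mix64(0xC2B2AE3D27D4EB4FULL + (uint64_t)b);
    for (int r = 0; r < rows; ++r)
      h = mix64(h ^ ((uint64_t)(uint32_t)sig[b * rows + r] + 1ULL));
    out[b] = h31(h);
  }
  return out;
}

// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector x, IntegerVector y) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int xi = x[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (xi == y[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Semi-global Needleman-Wunsch with affine gaps (open penalty, zero
// extension) over an arbitrary similarity matrix; end gaps are free.
// Returns a 2-column 1-based matrix of aligned index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_nw_pairing(NumericMatrix s, double gap_open) {
  int n = s.nrow(), m = s.ncol();
  const double NEG = -1e30;
  // states: 0 = match, 1 = gap in y (move down), 2 = gap in x (move right)
  std::vector<double> M((n + 1) * (m + 1), NEG), Ix(M), Iy(M);
  std::vector<unsigned char> tbM(M.size(), 0), tbIx(M.size(), 0), tbIy(M.size(), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) { Ix[at(i, 0)] = 0.0; tbIx[at(i, 0)] = 1; }
  for (int j = 1; j <= m; ++j) { Iy[at(0, j)] = 0.0; tbIy[at(0, j)] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1), c = at(i, j);
      // M
      double best = M[d]; unsigned char tb = 0;
      if (Ix[d] > best) { best = Ix[d]; tb = 1; }
      if (Iy[d] > best) { best = Iy[d]; tb = 2; }
      M[c] = best + s(i - 1, j - 1); tbM[c] = tb;
      // Ix: gap in y, consumes x (free if j == m)
      double go = (j == m) ? 0.0 : gap_open;
      best = M[u] + go; tb = 0;
      if (Ix[u] > best) { best = Ix[u]; tb = 1; }
      Ix[c] = best; tbIx[c] = tb;
      // Iy: gap in x, consumes y (free if i == n)
      go = (i == n) ? 0.0 : gap_open;
      best = M[l] + go; tb = 0;
      if (Iy[l] > best) { best = Iy[l]; tb = 2; }
      Iy[c] = best; tbIy[c] = tb;
    }
  }
  int i = n, j = m, state;
  int c = at(n, m);
  if (M[c] >= Ix[c] && M[c] >= Iy[c]) state = 0;
  else if (Ix[c] >= Iy[c]) state = 1;
  else state = 2;
  std::vector<int> ai, aj;
  while (i > 0 || j > 0) {
    int cc = at(i, j);
    if (state == 0) {
      ai.push_back(i); aj.push_back(j);
      state = tbM[cc]; --i; --j;
    } else if (state == 1) {
      state = tbIx[cc]; --i;
    } else {
      state = tbIy[cc]; --j;
    }
  }
  int k = ai.size();
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(t, 0) = ai[k - 1 - t];
    out(t, 1) = aj[k - 1 - t];
  }
  return out;
}
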
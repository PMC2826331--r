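#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>

using namespace Rcpp;

// Greedy colinear chaining of q-gram seed hits. Seeds must be sorted by
// (tpos, spos). A seed joins the active chain with the nearest diagonal
// among those whose last seed lies within max_gap on the reference and
// within diag_band in diagonal; otherwise it opens a new chain. Returns one
// row per chain: sb, se, tb, te (seed start extents) and the seed count.
// [[Rcpp::export]]
IntegerMatrix chain_seeds_cpp(IntegerVector spos, IntegerVector tpos,
                              int max_gap, int diag_band) {
  const int n = spos.size();
  std::vector<int> c_sb, c_se, c_tb, c_te, c_n;      // per-chain summaries
  std::vector<int> act_id, act_t, act_diag;          // active chain state
  for (int i = 0; i < n; ++i) {
    const int s = spos[i], t = tpos[i], d = t - s;
    // retire chains that can no longer be extended
    size_t w = 0;
    for (size_t k = 0; k < act_id.size(); ++k) {
      if (t - act_t[k] <= max_gap) {
        act_id[w] = act_id[k]; act_t[w] = act_t[k]; act_diag[w] = act_diag[k];
        ++w;
      }
    }
    act_id.resize(w); act_t.resize(w); act_diag.resize(w);
    int hit = -1, best = diag_band + 1;
    for (size_t k = 0; k < act_id.size(); ++k) {
      int dd = d - act_diag[k]; if (dd < 0) dd = -dd;
      if (dd < best) { best = dd; hit = (int)k; }
    }
    if (hit >= 0) {
      const int id = act_id[hit];
      act_t[hit] = t; act_diag[hit] = d;
      if (s < c_sb[id]) c_sb[id] = s;
      if (s > c_se[id]) c_se[id] = s;
      if (t < c_tb[id]) c_tb[id] = t;
      if (t > c_te[id]) c_te[id] = t;
      ++c_n[id];
    } else {
      act_id.push_back((int)c_sb.size());
      act_t.push_back(t); act_diag.push_back(d);
      c_sb.push_back(s); c_se.push_back(s);
      c_tb.push_back(t); c_te.push_back(t); c_n.push_back(1);
    }
  }
  IntegerMatrix out((int)c_sb.size(), 5);
  for (int k = 0; k < (int)c_sb.size(); ++k) {
    out(k, 0) = c_sb[k]; out(k, 1) = c_se[k]; out(k, 2) = c_tb[k];
    out(k, 3) = c_te[k]; out(k, 4) = c_n[k];
  }
  return out;
}

// Banded unit-cost edit distance (Levenshtein) between two strings.
// Cells outside the band |i - j| > band are treated as unreachable, so the
// result is an upper bound that equals the true distance whenever the optimal
// alignment stays within the band. 'N' never matches anything, itself
// included. Returns -1 if no within-band alignment exists.
// [[Rcpp::export]]
int banded_edit_distance(std::string a, std::string b, int band) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (band < 1) band = 1;
  // the band must at least absorb the length difference
  int need = m - n; if (need < 0) need = -need;
  if (band < need + 1) band = need + 1;
  const int width = 2 * band + 1;
  const int BIG = INT_MAX / 4;
  std::vector<int> prev(width, BIG), cur(width, BIG);
  // row i stores columns j in [i - band, i + band]; offset k = j - i + band
  for (int k = 0; k < width; ++k) {
    int j = 0 - 0 + k - band; // row 0
    if (j >= 0 && j <= m) prev[k] = j;
  }
  for (int i = 1; i <= n; ++i) {
    for (int k = 0; k < width; ++k) cur[k] = BIG;
    int jlo = i - band; if (jlo < 0) jlo = 0;
    int jhi = i + band; if (jhi > m) jhi = m;
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + band;
      int best = BIG;
      // deletion from a (vertical): prev row, same column j => offset k+1
      if (k + 1 < width && prev[k + 1] < BIG) {
        int v = prev[k + 1] + 1;
        if (v < best) best = v;
      }
      // insertion (horizontal): same row, column j-1 => offset k-1
      if (k - 1 >= 0 && cur[k - 1] < BIG) {
        int v = cur[k - 1] + 1;
        if (v < best) best = v;
      }
      // match/mismatch (diagonal): prev row, column j-1 => same offset k
      if (j >= 1 && prev[k] < BIG) {
        char ca = a[i - 1], cb = b[j - 1];
        bool match = (ca == cb) && ca != 'N' && ca != 'n';
        int v = prev[k] + (match ? 0 : 1);
        if (v < best) best = v;
      }
      cur[k] = best;
    }
    std::swap(prev, cur);
  }
  int k = m - n + band;
  if (k < 0 || k >= width || prev[k] >= BIG) return -1;
  return prev[k];
}
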
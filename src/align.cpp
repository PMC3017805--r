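#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman), optionally restricted to a
// diagonal band lo <= j - i <= hi (0-based diagonals).  A gap of length L
// costs gap_open + L * gap_ext.  The DP is exact within the band; calling
// with a band covering every diagonal gives the exhaustive solution.
//
// Ties on the best score keep the first-encountered cell scanning i then j
// ascending, i.e. the alignment with the leftmost end points.

static const int NEG = -1000000000;

// [[Rcpp::export]]
List c_align_band(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext,
                  int lo, int hi) {
  const int n = (int)a.size(), m = (int)b.size();
  if (lo < -n) lo = -n;
  if (hi > m) hi = m;
  if (lo > hi) return List::create(Named("score") = 0);
  const int W = hi - lo + 2; // one guard column each side handled via checks
  // band index for cell (i,j): k = j - i - lo, valid in [0, W-2]
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  std::vector<uint8_t> ph((size_t)(n + 1) * W, 0), pe((size_t)(n + 1) * W, 0),
      pf((size_t)(n + 1) * W, 0);
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };

  int best = 0, bi = -1, bk = -1;
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - i - lo;
      // E: gap in a (consume b) -> from (i, j-1) = k-1 same row
      int e = NEG, eptr = 0;
      if (k - 1 >= 0 && j - 1 >= i + lo) {
        int fromH = H[idx(i, k - 1)] - gap_open - gap_ext;
        int fromE = E[idx(i, k - 1)] - gap_ext;
        if (fromE > fromH) { e = fromE; eptr = 1; } else { e = fromH; eptr = 0; }
      }
      // F: gap in b (consume a) -> from (i-1, j) = k+1 previous row
      int f = NEG, fptr = 0;
      if (k + 1 <= W - 2 && j - (i - 1) <= hi) {
        int fromH = H[idx(i - 1, k + 1)] - gap_open - gap_ext;
        int fromF = F[idx(i - 1, k + 1)] - gap_ext;
        if (fromF > fromH) { f = fromF; fptr = 1; } else { f = fromH; fptr = 0; }
      }
      // diagonal: (i-1, j-1) = same k previous row
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int d = H[idx(i - 1, k)] + s;
      int h = 0; uint8_t hp = 0;
      if (d > h) { h = d; hp = 1; }
      if (e > h) { h = e; hp = 2; }
      if (f > h) { h = f; hp = 3; }
      H[idx(i, k)] = h; ph[idx(i, k)] = hp;
      E[idx(i, k)] = e; pe[idx(i, k)] = (uint8_t)eptr;
      F[idx(i, k)] = f; pf[idx(i, k)] = (uint8_t)fptr;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (best <= 0 || bi < 0)
    return List::create(Named("score") = 0);

  // traceback from (bi, bk) in state H
  std::string aa, bb;
  int i = bi, k = bk;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int a_end = bi, b_end = bi + k + lo;
  while (true) {
    int j = i + k + lo;
    if (state == 0) {
      uint8_t p = ph[idx(i, k)];
      if (p == 0) break;
      if (p == 1) {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        i -= 1; // k unchanged
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t p = pe[idx(i, k)];
      aa.push_back('-'); bb.push_back(b[j - 1]);
      k -= 1;
      state = (p == 1) ? 1 : 0;
    } else {
      uint8_t p = pf[idx(i, k)];
      aa.push_back(a[i - 1]); bb.push_back('-');
      i -= 1; k += 1;
      state = (p == 1) ? 2 : 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int a_start = i + 1, b_start = i + k + lo + 1;
  return List::create(
      Named("score") = best,
      Named("a_start") = a_start, Named("a_end") = a_end,
      Named("b_start") = b_start, Named("b_end") = b_end,
      Named("a_aln") = aa, Named("b_aln") = bb);
}

// Best gap-free local segment over all diagonals (maximal-scoring subarray
// per diagonal); exact, O(nm).
// [[Rcpp::export]]
List c_align_ungapped(std::string a, std::string b, int match, int mismatch) {
  const int n = (int)a.size(), m = (int)b.size();
  int best = 0, ba_end = -1, bb_end = -1, blen = 0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = std::max(0, -d); // a index (0-based) where diagonal enters
    int len = std::min(n - i0, m - (i0 + d));
    int run = 0, run_start = 0; // score of current subarray, its start offset
    for (int t = 0; t < len; ++t) {
      int i = i0 + t, j = i + d;
      int s = (a[i] == b[j]) ? match : mismatch;
      if (run <= 0) { run = s; run_start = t; }
      else run += s;
      if (run > best) {
        best = run; ba_end = i; bb_end = j; blen = t - run_start + 1;
      }
    }
  }
  if (best <= 0) return List::create(Named("score") = 0);
  int a_start = ba_end - blen + 2, b_start = bb_end - blen + 2; // 1-based
  std::string aa = a.substr(a_start - 1, blen), bb = b.substr(b_start - 1, blen);
  return List::create(
      Named("score") = best,
      Named("a_start") = a_start, Named("a_end") = ba_end + 1,
      Named("b_start") = b_start, Named("b_end") = bb_end + 1,
      Named("a_aln") = aa, Named("b_aln") = bb);
}

// Length of the longest exact substring shared by a and b (0 if none).
// [[Rcpp::export]]
int c_longest_common_substring(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}

// Longest gap-free window with at most max_mm mismatches over all diagonals.
// Ties keep the first window found scanning diagonals then positions.
// [[Rcpp::export]]
List c_longest_mismatch_window(std::string a, std::string b, int max_mm) {
  const int n = (int)a.size(), m = (int)b.size();
  int best = 0, ba = -1, bb = -1, bmm = 0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = std::max(0, -d);
    int len = std::min(n - i0, m - (i0 + d));
    if (len <= best) continue;
    // two pointers over the diagonal
    std::vector<int> mmpos;
    int left = 0; size_t mmlo = 0;
    for (int t = 0; t < len; ++t) {
      int i = i0 + t, j = i + d;
      if (a[i] != b[j]) mmpos.push_back(t);
      while ((int)(mmpos.size() - mmlo) > max_mm) {
        left = mmpos[mmlo] + 1;
        ++mmlo;
      }
      int w = t - left + 1;
      if (w > best) {
        best = w; ba = i0 + left; bb = i0 + left + d;
        bmm = (int)(mmpos.size() - mmlo);
      }
    }
  }
  if (best == 0) return List::create(Named("length") = 0);
  return List::create(
      Named("length") = best, Named("mismatches") = bmm,
      Named("a_start") = ba + 1, Named("a_end") = ba + best,
      Named("b_start") = bb + 1, Named("b_end") = bb + best);
}

// Diagonal range (min, max of j - i, 0-based) over shared k-mers; integer(0)
// if the sequences share no k-mer.
// [[Rcpp::export]]
IntegerVector c_seed_diag_range(std::string a, std::string b, int k) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n < k || m < k) return IntegerVector(0);
  std::unordered_map<std::string, std::vector<int>> pos;
  pos.reserve(n * 2);
  for (int i = 0; i + k <= n; ++i) pos[a.substr(i, k)].push_back(i);
  bool any = false;
  int lo = 0, hi = 0;
  for (int j = 0; j + k <= m; ++j) {
    auto it = pos.find(b.substr(j, k));
    if (it == pos.end()) continue;
    for (int i : it->second) {
      int d = j - i;
      if (!any) { lo = hi = d; any = true; }
      else { if (d < lo) lo = d; if (d > hi) hi = d; }
    }
  }
  if (!any) return IntegerVector(0);
  return IntegerVector::create(lo, hi);
}

// All unordered pairs of sequences sharing at least one k-mer.  k-mers seen
// in more than max_occ sequences are skipped (low-complexity guard).
// Returns a 2-column integer matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix c_kmer_candidate_pairs(CharacterVector seqs, int k, int max_occ) {
  const int N = seqs.size();
  std::unordered_map<std::string, std::vector<int>> occ;
  for (int s = 0; s < N; ++s) {
    std::string q = as<std::string>(seqs[s]);
    std::unordered_map<std::string, bool> seen;
    for (int i = 0; i + k <= (int)q.size(); ++i) {
      std::string km = q.substr(i, k);
      if (seen.count(km)) continue;
      seen[km] = true;
      occ[km].push_back(s);
    }
  }
  std::unordered_map<int64_t, bool> pairs;
  for (auto &kv : occ) {
    std::vector<int> &v = kv.second;
    if ((int)v.size() > max_occ) continue;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        pairs[(int64_t)v[x] * N + v[y]] = true;
  }
  IntegerMatrix out((int)pairs.size(), 2);
  int r = 0;
  std::vector<int64_t> keys;
  keys.reserve(pairs.size());
  for (auto &kv : pairs) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (int64_t key : keys) {
    out(r, 0) = (int)(key / N) + 1;
    out(r, 1) = (int)(key % N) + 1;
    ++r;
  }
  return out;
}
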
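#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
using namespace Rcpp;

// Suffix array by prefix doubling. Input is the text as integer codes
// ($ = 0 < A = 1 < C = 2 < G = 3 < T = 4); comparisons are on rank pairs,
// so repetitive inputs do not degrade to quadratic behaviour.
// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector text) {
  int n = text.size();
  if (n == 0) stop("empty text");
  std::vector<int> sa(n), rk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rk[i] = text[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      int ra = a + k < n ? rk[a + k] : -1;
      int rb = b + k < n ? rk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rk = tmp;
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// Kasai's algorithm: lcp[i] = length of the longest common prefix of the
// suffixes ranked i-1 and i; lcp[0] = 0.
// [[Rcpp::export]]
IntegerVector cpp_lcp_kasai(IntegerVector text, IntegerVector sa) {
  int n = text.size();
  IntegerVector lcp(n);
  std::vector<int> rank_(n);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      lcp[0] = 0;
      h = 0;
    }
  }
  return lcp;
}

// Per-run, per-character repositioning thresholds. For run i and character
// c != run character, returns the offset t in [0, len] such that offsets
// < t reposition up and offsets >= t reposition down. The direction for a
// row is the one whose nearest c-carrying row has the larger range-minimum
// LCP with the current row; ties break upward. t = len when c never occurs
// below the run, t = 0 when it never occurs above, NA when c is absent from
// the BWT entirely (and for the run's own character).
// [[Rcpp::export]]
IntegerMatrix cpp_thresholds(IntegerVector bwt, IntegerVector lcp,
                             IntegerVector run_start, IntegerVector run_len,
                             IntegerVector run_char) {
  int n = bwt.size(), r = run_start.size();
  IntegerMatrix thr(r, 4);
  std::fill(thr.begin(), thr.end(), NA_INTEGER);
  std::vector<int> upL(n), downL(n);
  for (int c = 1; c <= 4; ++c) {
    // upL[x] = min lcp over (u, x] where u is the nearest row above with
    // bwt == c; -1 when no such row.
    long lastc = -1;
    int rm = INT_MAX;
    for (int x = 0; x < n; ++x) {
      if (x > 0 && bwt[x - 1] == c) { lastc = x - 1; rm = INT_MAX; }
      if (lastc >= 0) { rm = std::min(rm, lcp[x]); upL[x] = rm; }
      else upL[x] = -1;
    }
    // downL[x] = min lcp over (x, d] where d is the nearest row below.
    long nextc = -1;
    rm = INT_MAX;
    for (int x = n - 1; x >= 0; --x) {
      if (x < n - 1 && bwt[x + 1] == c) { nextc = x + 1; rm = INT_MAX; }
      if (nextc >= 0) { rm = std::min(rm, lcp[x + 1]); downL[x] = rm; }
      else downL[x] = -1;
    }
    for (int i = 0; i < r; ++i) {
      if (run_char[i] == c) continue;
      int s = run_start[i], L = run_len[i];
      if (upL[s] < 0 && downL[s] < 0) continue;  // character absent: NA
      int t = L;
      for (int j = 0; j < L; ++j) {
        int x = s + j;
        int u = upL[x], d = downL[x];
        // down wins only strictly (ties break upward); up/down LCPs are
        // monotone across the run, so the first down-win is the threshold
        bool down = (u < 0) ? true : (d < 0 ? false : d > u);
        if (down) { t = j; break; }
      }
      thr(i, c - 1) = t;
    }
  }
  return thr;
}

// LF destination of each run head, expressed both as a global row and as a
// (destination run, offset) pair. Equivalent to rank-based LF on the full
// BWT evaluated at run starts.
// [[Rcpp::export]]
List cpp_move_table(IntegerVector run_start, IntegerVector run_len,
                    IntegerVector run_char, IntegerVector char_counts) {
  int r = run_start.size();
  long base[5];
  long acc = 0;
  for (int c = 0; c < 5; ++c) { base[c] = acc; acc += char_counts[c]; }
  std::vector<long> seen(5, 0);
  IntegerVector dest_run(r), dest_off(r), lf_head(r);
  for (int i = 0; i < r; ++i) {
    int c = run_char[i];
    long lf = base[c] + seen[c];
    lf_head[i] = (int)lf;
    seen[c] += run_len[i];
  }
  for (int i = 0; i < r; ++i) {
    int lf = lf_head[i];
    int g = (int)(std::upper_bound(run_start.begin(), run_start.end(), lf) -
                  run_start.begin()) - 1;
    dest_run[i] = g;
    dest_off[i] = lf - run_start[g];
  }
  return List::create(_["dest_run"] = dest_run, _["dest_offset"] = dest_off,
                      _["lf_head"] = lf_head);
}

// Nearest run above/below each run carrying each character (A,C,G,T).
// -1 when no such run exists. The run's own entry for its own character is
// never consulted and is also filled with the nearest *other* run.
// [[Rcpp::export]]
List cpp_nearest_runs(IntegerVector run_char) {
  int r = run_char.size();
  IntegerMatrix up(r, 4), down(r, 4);
  for (int c = 1; c <= 4; ++c) {
    int last = -1;
    for (int i = 0; i < r; ++i) {
      up(i, c - 1) = last;
      if (run_char[i] == c) last = i;
    }
    int nxt = -1;
    for (int i = r - 1; i >= 0; --i) {
      down(i, c - 1) = nxt;
      if (run_char[i] == c) nxt = i;
    }
  }
  return List::create(_["up"] = up, _["down"] = down);
}

// Distinct document IDs per run (set semantics), skipping the no-document
// sentinel (-1). Returns a list of sorted integer vectors.
// [[Rcpp::export]]
List cpp_run_doc_sets(IntegerVector doc_array, IntegerVector run_start,
                      IntegerVector run_len) {
  int r = run_start.size();
  List out(r);
  std::vector<int> buf;
  for (int i = 0; i < r; ++i) {
    buf.clear();
    for (int j = 0; j < run_len[i]; ++j) {
      int d = doc_array[run_start[i] + j];
      if (d >= 0) buf.push_back(d);
    }
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
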
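#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Shared walk machinery for PML queries over the move table.
// Positions are (run i, offset j) pairs; strategies: 0 = lcp_thresholds,
// 1 = mid_run, 2 = always_up.

static inline bool choose_up(int strategy, int j, int run_len_i, int thr_val,
                             int upi, int dni) {
  bool goUp;
  if (strategy == 0) {
    goUp = (j < thr_val);
  } else if (strategy == 1) {
    goUp = (j < (run_len_i + 1) / 2);
    if (goUp && upi < 0) goUp = false;
    if (!goUp && dni < 0) goUp = true;
  } else {
    goUp = (upi >= 0);
  }
  return goUp;
}

// PML computation with color tallying. Processes the read right-to-left
// from the position of BWT[n-1]; case 1 (run character matches) increments
// the length, case 2 repositions and resets it to 0. Whenever the fixed
// length is positive the color of the current run is tallied into the
// per-document scores. Characters absent from the index give length 0 with
// no movement. Color sets are passed in CSR form (0-based).
// [[Rcpp::export]]
List cpp_query_pml(IntegerVector read, int strategy, IntegerVector run_char,
                   IntegerVector run_len, IntegerVector dest_run,
                   IntegerVector dest_off, IntegerMatrix thr,
                   IntegerMatrix up_run, IntegerMatrix down_run,
                   IntegerVector run_color, IntegerVector color_ptr,
                   IntegerVector color_docs, int n_docs,
                   LogicalVector char_present, bool record) {
  int m = read.size(), r = run_char.size();
  IntegerVector pml(m);
  IntegerVector scores(n_docs);
  IntegerVector pos_color(record ? m : 0);
  IntegerVector pos_run(record ? m : 0);
  int i = r - 1, j = run_len[r - 1] - 1, len = 0;
  for (int k = m - 1; k >= 0; --k) {
    int c = read[k];
    if (c < 1 || c > 4 || !char_present[c]) {
      len = 0;
      pml[k] = 0;
      if (record) { pos_color[k] = -1; pos_run[k] = -1; }
      continue;
    }
    if (run_char[i] == c) {
      ++len;
    } else {
      int upi = up_run(i, c - 1), dni = down_run(i, c - 1);
      bool goUp = choose_up(strategy, j, run_len[i], thr(i, c - 1), upi, dni);
      if (goUp) { i = upi; j = run_len[i] - 1; }
      else      { i = dni; j = 0; }
      len = 0;
    }
    pml[k] = len;
    if (len > 0) {
      int cid = run_color[i];
      for (int p = color_ptr[cid]; p < color_ptr[cid + 1]; ++p)
        scores[color_docs[p]]++;
      if (record) { pos_color[k] = cid; pos_run[k] = i; }
    } else if (record) {
      pos_color[k] = -1; pos_run[k] = -1;
    }
    // LF step with fast-forward through following runs
    int di = dest_run[i];
    long off = (long)dest_off[i] + j;
    while (off >= run_len[di]) { off -= run_len[di]; ++di; }
    i = di;
    j = (int)off;
  }
  List out = List::create(_["pml"] = pml, _["scores"] = scores);
  if (record) { out["pos_color"] = pos_color; out["pos_run"] = pos_run; }
  return out;
}

static inline long rank_at(long row, int c, IntegerVector run_start,
                           IntegerVector run_char, IntegerMatrix cum,
                           long n, int r) {
  if (row >= n) return cum(r, c);
  int g = (int)(std::upper_bound(run_start.begin(), run_start.end(), (int)row) -
                run_start.begin()) - 1;
  long rk = cum(g, c);
  if (run_char[g] == c) rk += row - run_start[g];
  return rk;
}

// PML walk that additionally maintains the backward-search interval of the
// current match, so that for every position with PML >= min_len it can
// compare the color's document set against the true set of documents
// containing that exact match (distinct doc_array entries over the SA
// interval). Returns per-position PMLs and Jaccard similarities (NA where
// PML < min_len). cum is the (r+1) x 5 matrix of per-run cumulative
// character counts.
// [[Rcpp::export]]
List cpp_query_pml_fidelity(IntegerVector read, int strategy,
                            IntegerVector run_char, IntegerVector run_len,
                            IntegerVector run_start, IntegerVector dest_run,
                            IntegerVector dest_off, IntegerMatrix thr,
                            IntegerMatrix up_run, IntegerMatrix down_run,
                            IntegerVector run_color, IntegerVector color_ptr,
                            IntegerVector color_docs, int n_docs,
                            LogicalVector char_present, IntegerMatrix cum,
                            IntegerVector doc_array, int min_len) {
  int m = read.size(), r = run_char.size();
  long n = doc_array.size();
  long base[5];
  {
    long acc = 0;
    for (int c = 0; c < 5; ++c) { base[c] = acc; acc += cum(r, c); }
  }
  IntegerVector pml(m);
  NumericVector jac(m, NA_REAL);       // single-run color vs truth
  NumericVector jac_tally(m, NA_REAL); // running streak intersection vs truth
  std::vector<int> stamp(n_docs, -1);
  std::vector<int> truth_docs;
  std::vector<int> inter_set, tmp_set;
  int i = r - 1, j = run_len[r - 1] - 1, len = 0;
  long sp = 0, ep = 0;
  for (int k = m - 1; k >= 0; --k) {
    int c = read[k];
    if (c < 1 || c > 4 || !char_present[c]) { len = 0; pml[k] = 0; continue; }
    if (run_char[i] == c) {
      long osp = (len == 0) ? 0 : sp;
      long oep = (len == 0) ? n : ep;
      sp = base[c] + rank_at(osp, c, run_start, run_char, cum, n, r);
      ep = base[c] + rank_at(oep, c, run_start, run_char, cum, n, r);
      ++len;
    } else {
      int upi = up_run(i, c - 1), dni = down_run(i, c - 1);
      bool goUp = choose_up(strategy, j, run_len[i], thr(i, c - 1), upi, dni);
      if (goUp) { i = upi; j = run_len[i] - 1; }
      else      { i = dni; j = 0; }
      len = 0;
    }
    pml[k] = len;
    if (len > 0) {
      // documents the tallied colors imply for the current match: those
      // scored at every step of the case-1 streak so far (the running
      // intersection of the encountered colors)
      int cid0 = run_color[i];
      if (len == 1) {
        inter_set.assign(color_docs.begin() + color_ptr[cid0],
                         color_docs.begin() + color_ptr[cid0 + 1]);
      } else {
        tmp_set.clear();
        int p = color_ptr[cid0], pe = color_ptr[cid0 + 1];
        for (int d : inter_set) {
          while (p < pe && color_docs[p] < d) ++p;
          if (p < pe && color_docs[p] == d) tmp_set.push_back(d);
        }
        inter_set.swap(tmp_set);
      }
    }
    if (len >= min_len && len > 0) {
      truth_docs.clear();
      for (long x = sp; x < ep; ++x) {
        int d = doc_array[x];
        if (d >= 0 && stamp[d] != k) { stamp[d] = k; truth_docs.push_back(d); }
      }
      int cid = run_color[i];
      int inter = 0, csize = color_ptr[cid + 1] - color_ptr[cid];
      for (int p = color_ptr[cid]; p < color_ptr[cid + 1]; ++p)
        if (stamp[color_docs[p]] == k) ++inter;
      int uni = (int)truth_docs.size() + csize - inter;
      jac[k] = uni > 0 ? (double)inter / uni : NA_REAL;
      int inter2 = 0;
      for (int d : inter_set) if (stamp[d] == k) ++inter2;
      int uni2 = (int)truth_docs.size() + (int)inter_set.size() - inter2;
      jac_tally[k] = uni2 > 0 ? (double)inter2 / uni2 : NA_REAL;
    }
    int di = dest_run[i];
    long off = (long)dest_off[i] + j;
    while (off >= run_len[di]) { off -= run_len[di]; ++di; }
    i = di;
    j = (int)off;
  }
  return List::create(_["pml"] = pml, _["jaccard_run"] = jac,
                      _["jaccard"] = jac_tally);
}
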
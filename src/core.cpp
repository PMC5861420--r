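#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Encoding used throughout: 0 = N, 1 = A, 2 = C, 3 = G, 4 = T.
// Count matrices are 5 x W numeric: row 0 (R row 1) holds N counts, rows
// 1..4 the A/C/G/T counts.  Column totals N_i exclude the N row, so padding
// is uninformative missing data.

static inline int comp_base(int b) { return b == 0 ? 0 : 5 - b; }

// Base occupying window position i for configuration (offset, strand).
// strand: 1 = forward, 2 = reverse.  Reverse windows are the reverse
// complement of the forward extraction at the mirrored offset L - W - off,
// which simplifies to reading position L - 1 - off - i and complementing.
static inline int win_base(const int* s, int L, int off, int strand, int W,
                           int i) {
  int p = (strand == 1) ? (off + i) : (L - 1 - off - i);
  int b = (p >= 0 && p < L) ? s[p] : 0;
  return (strand == 1) ? b : comp_base(b);
}

// Admissible forward offsets: -floor(W/2) .. L - ceil(W/2) - 1, so at least
// ceil(W/2) window positions overlap the sequence.  Falls back to the single
// centred offset when the range is empty (tiny L) or shifts are disabled.
static void offset_range(int L, int W, bool shifts, int& omin, int& omax) {
  if (shifts) {
    omin = -(W / 2);
    omax = L - (W + 1) / 2 - 1;
    if (omax >= omin) return;
  }
  // floor((L - W) / 2) with correct behaviour for negative L - W
  int d = L - W;
  omin = omax = (d >= 0) ? d / 2 : -(( -d + 1) / 2);
}

// [[Rcpp::export]]
IntegerVector cpp_offsets(int L, int W, bool shifts) {
  int omin, omax;
  offset_range(L, W, shifts, omin, omax);
  IntegerVector out(omax - omin + 1);
  for (int o = omin; o <= omax; ++o) out[o - omin] = o;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_window(IntegerVector seq, int off, int strand, int W) {
  IntegerVector w(W);
  int L = seq.size();
  const int* s = INTEGER(seq);
  for (int i = 0; i < W; ++i) w[i] = win_base(s, L, off, strand, W, i);
  return w;
}

// Per-config log-likelihood matrix from counts: 5 x W, row 0 = log(1/4) for
// N, rows 1..4 = log((n + c) / (N_i + 4c)).
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(NumericMatrix counts, double c) {
  int W = counts.ncol();
  NumericMatrix sm(5, W);
  double lq = std::log(0.25);
  for (int i = 0; i < W; ++i) {
    double tot = 0.0;
    for (int b = 1; b < 5; ++b) tot += counts(b, i);
    double den = std::log(tot + 4.0 * c);
    sm(0, i) = lq;
    for (int b = 1; b < 5; ++b) sm(b, i) = std::log(counts(b, i) + c) - den;
  }
  return sm;
}

static double score_config(const int* s, int L, int off, int strand, int W,
                           const NumericMatrix& sm) {
  double sc = 0.0;
  for (int i = 0; i < W; ++i) sc += sm(win_base(s, L, off, strand, W, i), i);
  return sc;
}

// Best (offset, strand) over all admissible configurations.  Ties broken
// deterministically: smallest offset first, forward before reverse.
// [[Rcpp::export]]
List cpp_best_window(IntegerVector seq, NumericMatrix sm, bool shifts,
                     bool rc) {
  int W = sm.ncol(), L = seq.size();
  const int* s = INTEGER(seq);
  int omin, omax;
  offset_range(L, W, shifts, omin, omax);
  double best = R_NegInf;
  int boff = omin, bstr = 1;
  for (int off = omin; off <= omax; ++off) {
    int smax = rc ? 2 : 1;
    for (int strand = 1; strand <= smax; ++strand) {
      double sc = score_config(s, L, off, strand, W, sm);
      if (sc > best) {
        best = sc;
        boff = off;
        bstr = strand;
      }
    }
  }
  return List::create(_["offset"] = boff, _["strand"] = bstr,
                      _["score"] = best);
}

// Scores of every configuration, forward offsets then (if rc) reverse
// offsets, offsets ascending within strand.  Used by tests as a flat view.
// [[Rcpp::export]]
NumericMatrix cpp_all_scores(IntegerVector seq, NumericMatrix sm, bool shifts,
                             bool rc) {
  int W = sm.ncol(), L = seq.size();
  const int* s = INTEGER(seq);
  int omin, omax;
  offset_range(L, W, shifts, omin, omax);
  int n = omax - omin + 1;
  int rows = rc ? 2 * n : n;
  NumericMatrix out(rows, 3);  // offset, strand, score
  int k = 0;
  for (int strand = 1; strand <= (rc ? 2 : 1); ++strand)
    for (int off = omin; off <= omax; ++off, ++k) {
      out(k, 0) = off;
      out(k, 1) = strand;
      out(k, 2) = score_config(s, L, off, strand, W, sm);
    }
  return out;
}

static void counts_update(NumericMatrix& counts, const int* s, int L, int off,
                          int strand, int W, double delta) {
  for (int i = 0; i < W; ++i)
    counts(win_base(s, L, off, strand, W, i), i) += delta;
}

// [[Rcpp::export]]
NumericMatrix cpp_counts(List seqs, IntegerVector members, IntegerVector offs,
                         IntegerVector strands, int W) {
  NumericMatrix counts(5, W);
  int M = members.size();
  for (int m = 0; m < M; ++m) {
    IntegerVector s = seqs[members[m] - 1];
    counts_update(counts, INTEGER(s), s.size(), offs[m], strands[m], W, 1.0);
  }
  return counts;
}

// Leave-one-out log-likelihood (Eq 2 with the member's own window removed
// from the counts) for every member of a cluster.
// [[Rcpp::export]]
NumericVector cpp_loo_scores(List seqs, IntegerVector members,
                             IntegerVector offs, IntegerVector strands,
                             NumericMatrix counts, double c) {
  int W = counts.ncol();
  int M = members.size();
  NumericVector out(M);
  std::vector<double> tot(W, 0.0);
  for (int i = 0; i < W; ++i)
    for (int b = 1; b < 5; ++b) tot[i] += counts(b, i);
  double lq = std::log(0.25);
  for (int m = 0; m < M; ++m) {
    IntegerVector s = seqs[members[m] - 1];
    const int* sp = INTEGER(s);
    int L = s.size();
    double sc = 0.0;
    for (int i = 0; i < W; ++i) {
      int b = win_base(sp, L, offs[m], strands[m], W, i);
      if (b == 0)
        sc += lq;
      else
        sc += std::log(counts(b, i) - 1.0 + c) - std::log(tot[i] - 1.0 + 4.0 * c);
    }
    out[m] = sc;
  }
  return out;
}

// Iterative two-cluster refinement: in each sweep the members are visited in
// fresh random order (R's RNG), removed from their cluster, scored with the
// full window search against both clusters, and inserted into the more
// likely one.  Stops at a sweep with no membership or window change, or at
// maxSweeps.  Returns the fixed point plus bookkeeping.
// [[Rcpp::export]]
List cpp_refine(List seqs, IntegerVector members, IntegerVector membership,
                IntegerVector offs, IntegerVector strands, int W, double c,
                bool shifts, bool rc, int maxSweeps) {
  int M = members.size();
  IntegerVector mem = clone(membership);
  IntegerVector off = clone(offs);
  IntegerVector str = clone(strands);
  NumericMatrix c1(5, W), c2(5, W);
  for (int m = 0; m < M; ++m) {
    IntegerVector s = seqs[members[m] - 1];
    NumericMatrix& ct = (mem[m] == 1) ? c1 : c2;
    counts_update(ct, INTEGER(s), s.size(), off[m], str[m], W, 1.0);
  }
  int sweeps = 0;
  bool changed = true;
  while (changed && sweeps < maxSweeps) {
    ++sweeps;
    changed = false;
    IntegerVector ord = sample(M, M, false);  // 1-based, uses R's RNG
    for (int k = 0; k < M; ++k) {
      int m = ord[k] - 1;
      IntegerVector s = seqs[members[m] - 1];
      const int* sp = INTEGER(s);
      int L = s.size();
      NumericMatrix& cur = (mem[m] == 1) ? c1 : c2;
      counts_update(cur, sp, L, off[m], str[m], W, -1.0);
      NumericMatrix sm1 = cpp_score_matrix(c1, c);
      NumericMatrix sm2 = cpp_score_matrix(c2, c);
      List b1 = cpp_best_window(s, sm1, shifts, rc);
      List b2 = cpp_best_window(s, sm2, shifts, rc);
      double s1 = as<double>(b1["score"]), s2 = as<double>(b2["score"]);
      int newmem = (s2 > s1) ? 2 : 1;  // tie -> cluster 1
      List bb = (newmem == 1) ? b1 : b2;
      int noff = as<int>(bb["offset"]), nstr = as<int>(bb["strand"]);
      if (newmem != mem[m] || noff != off[m] || nstr != str[m]) changed = true;
      mem[m] = newmem;
      off[m] = noff;
      str[m] = nstr;
      NumericMatrix& dst = (newmem == 1) ? c1 : c2;
      counts_update(dst, sp, L, noff, nstr, W, 1.0);
    }
  }
  int n1 = 0;
  for (int m = 0; m < M; ++m)
    if (mem[m] == 1) ++n1;
  return List::create(_["membership"] = mem, _["offsets"] = off,
                      _["strands"] = str, _["counts1"] = c1,
                      _["counts2"] = c2, _["sweeps"] = sweeps,
                      _["size1"] = n1, _["size2"] = M - n1,
                      _["emptied"] = (n1 == 0 || n1 == M));
}
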
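#include <Rcpp.h>
using namespace Rcpp;

// Best-window PWM scan over a batch of integer-encoded sequences.
//
// Sequences are encoded 1=A, 2=C, 3=G, 4=T, 0=N; `w` is the 4 x L log-odds
// matrix. Every window on both strands is evaluated; windows containing an N
// are skipped. The minus-strand score of window [s, s+L) is the score of its
// reverse complement (complement code = 5 - code). Ties are broken by
// leftmost start, then plus strand, matching the documented calling order.
//
// Returns an n x 3 matrix: score, 0-based window start, strand (+1/-1).
// A row of NA marks a sequence with no scannable window.
// [[Rcpp::export(name = ".best_window_scan")]]
NumericMatrix best_window_scan(List seqs, NumericMatrix w) {
  const int L = w.ncol();
  const int n = seqs.size();
  NumericMatrix out(n, 3);

  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    const int len = s.size();
    double best = R_NegInf;
    int best_start = -1, best_strand = 0;

    for (int st = 0; st + L <= len; ++st) {
      bool ok = true;
      double fwd = 0.0, rev = 0.0;
      for (int j = 0; j < L; ++j) {
        const int cf = s[st + j];
        const int cr = s[st + L - 1 - j];
        if (cf == 0 || cr == 0) { ok = false; break; }
        fwd += w(cf - 1, j);
        rev += w(4 - cr, j); // complement of cr is 5 - cr; row index (5-cr)-1
      }
      if (!ok) continue;
      if (fwd > best) { best = fwd; best_start = st; best_strand = 1; }
      if (rev > best) { best = rev; best_start = st; best_strand = -1; }
    }

    if (best_start < 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
    } else {
      out(i, 0) = best; out(i, 1) = best_start; out(i, 2) = best_strand;
    }
  }
  return out;
}

// All forward+reverse window scores for one sequence (NaN where the window
// holds an N). Used by calibration code; column 1 forward, column 2 reverse.
// [[Rcpp::export(name = ".all_window_scores")]]
NumericMatrix all_window_scores(IntegerVector s, NumericMatrix w) {
  const int L = w.ncol();
  const int len = s.size();
  const int nw = len - L + 1 > 0 ? len - L + 1 : 0;
  NumericMatrix out(nw, 2);

  for (int st = 0; st < nw; ++st) {
    bool ok = true;
    double fwd = 0.0, rev = 0.0;
    for (int j = 0; j < L; ++j) {
      const int cf = s[st + j];
      const int cr = s[st + L - 1 - j];
      if (cf == 0 || cr == 0) { ok = false; break; }
      fwd += w(cf - 1, j);
      rev += w(4 - cr, j);
    }
    if (!ok) { out(st, 0) = NA_REAL; out(st, 1) = NA_REAL; }
    else     { out(st, 0) = fwd;     out(st, 1) = rev; }
  }
  return out;
}
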
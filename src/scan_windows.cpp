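#include <Rcpp.h>
using namespace Rcpp;

// Integer window scores for one integerized log-odds matrix over a coded
// sequence (A=0, C=1, G=2, T=3, N = NA). Windows containing N get NA.
// [[Rcpp::export]]
IntegerVector window_scores(IntegerVector codes, IntegerMatrix lom) {
  int n = codes.size(), L = lom.nrow();
  if (n < L) return IntegerVector(0);
  IntegerVector out(n - L + 1);
  for (int i = 0; i <= n - L; ++i) {
    long s = 0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      int c = codes[i + j];
      if (c == NA_INTEGER) { ok = false; break; }
      s += lom(j, c);
    }
    out[i] = ok ? (int)s : NA_INTEGER;
  }
  return out;
}

// Scan one coded peak sequence against a set of motifs on both strands.
// loms / loms_rc: per-motif integer log-odds matrices (forward and
// reverse-complement); thresholds: minimum integer score to report.
// Returns parallel vectors (motif index 1-based, 0-based window offset,
// strand "+"/"-", integer score). At a given (motif, offset) only the
// better-scoring strand is kept, ties resolved to "+".
// [[Rcpp::export]]
List scan_peak_hits(IntegerVector codes, List loms, List loms_rc,
                    IntegerVector thresholds) {
  std::vector<int> midx, off, sc;
  std::vector<std::string> strand;
  int n = codes.size();
  for (int m = 0; m < loms.size(); ++m) {
    IntegerMatrix lom = loms[m], lrc = loms_rc[m];
    int L = lom.nrow(), thr = thresholds[m];
    for (int i = 0; i + L <= n; ++i) {
      long sf = 0, sr = 0;
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        int c = codes[i + j];
        if (c == NA_INTEGER) { ok = false; break; }
        sf += lom(j, c);
        sr += lrc(j, c);
      }
      if (!ok) continue;
      bool fwd = sf >= sr;
      long best = fwd ? sf : sr;
      if (best >= thr) {
        midx.push_back(m + 1);
        off.push_back(i);
        sc.push_back((int)best);
        strand.push_back(fwd ? "+" : "-");
      }
    }
  }
  return List::create(_["motif"] = wrap(midx), _["offset"] = wrap(off),
                      _["strand"] = wrap(strand), _["score"] = wrap(sc));
}
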
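#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and full traceback.
// Scores: match, mismatch, gap (per gap base). Ties resolved diagonal-first,
// best cell taken at the first strict improvement in row-major order, so the
// reported alignment is deterministic.
//
// Returns one row per read: score, sub_start/sub_end (1-based on subject),
// read_start/read_end, n_match (identical columns), n_cols (alignment
// columns including gaps). Coordinates are NA when no positive-scoring
// alignment exists.
// [[Rcpp::export]]
DataFrame align_local_batch(CharacterVector reads, std::string subject,
                            double match = 1.0, double mismatch = -1.0,
                            double gap = -2.0) {
  const int n = reads.size();
  const int m = subject.size();
  NumericVector score(n);
  IntegerVector ss(n), se(n), rs(n), re(n), nm(n), nc(n);
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb;

  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int L = read.size();
    tb.assign((size_t)(L + 1) * (m + 1), 0);
    std::fill(prev.begin(), prev.end(), 0.0);
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= L; ++i) {
      cur[0] = 0.0;
      const char rc = read[i - 1];
      unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
      for (int j = 1; j <= m; ++j) {
        double v = prev[j - 1] + (rc == subject[j - 1] ? match : mismatch);
        unsigned char t = 1;               // diagonal
        const double up = prev[j] + gap;   // gap in subject (consumes read)
        if (up > v) { v = up; t = 2; }
        const double left = cur[j - 1] + gap;  // gap in read
        if (left > v) { v = left; t = 3; }
        if (v <= 0.0) { v = 0.0; t = 0; }
        cur[j] = v;
        tbrow[j] = t;
        if (v > best) { best = v; bi = i; bj = j; }
      }
      std::swap(prev, cur);
    }
    int i = bi, j = bj, matches = 0, cols = 0;
    while (i > 0 && j > 0) {
      const unsigned char t = tb[(size_t)i * (m + 1) + j];
      if (t == 0) break;
      ++cols;
      if (t == 1) { if (read[i - 1] == subject[j - 1]) ++matches; --i; --j; }
      else if (t == 2) { --i; }
      else { --j; }
    }
    score[r] = best;
    nm[r] = matches;
    nc[r] = cols;
    if (best > 0.0) {
      ss[r] = j + 1; se[r] = bj; rs[r] = i + 1; re[r] = bi;
    } else {
      ss[r] = NA_INTEGER; se[r] = NA_INTEGER;
      rs[r] = NA_INTEGER; re[r] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["score"] = score,
                           _["sub_start"] = ss, _["sub_end"] = se,
                           _["read_start"] = rs, _["read_end"] = re,
                           _["n_match"] = nm, _["n_cols"] = nc);
}
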
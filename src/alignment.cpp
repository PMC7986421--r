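#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;  // N matches nothing
    default: return -1;
  }
}

// Smith-Waterman local alignment score (Gotoh affine gaps, score only).
// Gap of length L costs gap_open + (L - 1) * gap_extend; penalties are
// supplied as non-positive numbers. An 'N' scores `mismatch` against every
// base including 'N'.
static double sw_score(const std::string &read, const std::string &ref,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = read.size(), m = ref.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<int> rd(n), rf(m);
  for (int i = 0; i < n; ++i) {
    rd[i] = base_code(read[i]);
    if (rd[i] < 0) stop("invalid character in read: '%c'", read[i]);
  }
  for (int j = 0; j < m; ++j) {
    rf[j] = base_code(ref[j]);
    if (rf[j] < 0) stop("invalid character in reference: '%c'", ref[j]);
  }
  const double NEG = -1e30;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = H[0];       // H[i-1][0]
    double F = NEG;           // vertical gap state, column-wise
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] + gap_open, E[j] + gap_extend);   // gap in read
      F = std::max(H[j - 1] + gap_open, F + gap_extend);     // gap in ref
      double s = (rd[i - 1] == rf[j - 1] && rd[i - 1] != 4) ? match : mismatch;
      double h = diag + s;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_batch")]]
NumericVector sw_score_batch(CharacterVector reads, std::string ref,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  if (match <= 0) stop("'match' must be > 0");
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0");
  const int n = reads.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    out[k] = sw_score(as<std::string>(reads[k]), ref,
                      match, mismatch, gap_open, gap_extend);
  }
  return out;
}
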
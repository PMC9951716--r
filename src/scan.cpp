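#include <Rcpp.h>
using namespace Rcpp;

// Smallest period of the k-mer starting at s[i]; equals k iff the motif is
// primitive (not a tandem repetition of a shorter unit).
static int smallest_period(const char *s, int i, int k) {
  for (int d = 1; d < k; ++d) {
    if (k % d != 0) continue;
    bool ok = true;
    for (int j = d; j < k && ok; ++j)
      if (s[i + j] != s[i + j - d]) ok = false;
    if (ok) return d;
  }
  return k;
}

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Left-to-right scan for maximal perfect tandem repeats with unit length
// 1..max_period. At each position the shortest qualifying primitive period
// wins; after a locus is accepted scanning resumes at its end, so reported
// loci never share a base. Coordinates are 0-based half-open.
// [[Rcpp::export]]
DataFrame scan_perfect_cpp(std::string seq, IntegerVector min_repeats,
                           int max_period) {
  const char *s = seq.c_str();
  const int n = (int) seq.size();
  if ((int) min_repeats.size() < max_period)
    stop("min_repeats must have one entry per motif length");

  std::vector<int> out_start, out_period, out_repeats;
  int i = 0;
  while (i < n) {
    if (!is_base(s[i])) { ++i; continue; }
    bool accepted = false;
    for (int p = 1; p <= max_period && i + p <= n; ++p) {
      bool motif_ok = true;
      for (int j = i; j < i + p; ++j)
        if (!is_base(s[j])) { motif_ok = false; break; }
      if (!motif_ok) break;          // an N inside the window blocks p and larger
      if (smallest_period(s, i, p) != p) continue;  // non-primitive unit
      int j = i + p;
      while (j < n && is_base(s[j]) && s[j] == s[j - p]) ++j;
      int repeats = (j - i) / p;
      if (repeats >= min_repeats[p - 1]) {
        out_start.push_back(i);
        out_period.push_back(p);
        out_repeats.push_back(repeats);
        i += repeats * p;
        accepted = true;
        break;
      }
    }
    if (!accepted) ++i;
  }
  return DataFrame::create(_["start"] = out_start, _["period"] = out_period,
                           _["repeats"] = out_repeats);
}

// Validate the alphabet; returns the 1-based position of the first character
// outside {A,C,G,T,N}, or 0 if the sequence is clean.
// [[Rcpp::export]]
int first_invalid_base_cpp(std::string seq) {
  const char *s = seq.c_str();
  for (int i = 0; i < (int) seq.size(); ++i)
    if (!is_base(s[i]) && s[i] != 'N') return i + 1;
  return 0;
}
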
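#include "common.h"
using namespace Rcpp;

// Identity of alignments to `ref` overall and outside homopolymer runs of
// length >= min_run (runs are masked including their flanking junctions).
// CIGARs must be resolved (=/X only for column classification).
// Returns per-alignment: cols_all, match_all, cols_out, match_out.
// [[Rcpp::export]]
NumericMatrix cpp_masked_identity(std::string ref, IntegerVector tstart,
                                  CharacterVector cigar, int min_run) {
  const long n = (long)ref.size();
  for (auto& c : ref) c = toupper(c);
  std::vector<bool> inrun(n, false);
  long i = 0;
  while (i < n) {
    long j = i + 1;
    while (j < n && ref[j] == ref[i]) ++j;
    if (j - i >= min_run)
      for (long p = i; p < j; ++p) inrun[p] = true;
    i = j;
  }
  NumericMatrix out(tstart.size(), 4);
  colnames(out) = CharacterVector::create("cols_all", "match_all",
                                          "cols_out", "match_out");
  for (int a = 0; a < tstart.size(); ++a) {
    std::vector<CigarOp> ops = parse_cigar(as<std::string>(cigar[a]));
    long t = tstart[a];
    double ca = 0, ma = 0, co = 0, mo = 0;
    for (const CigarOp& o : ops) {
      switch (o.op) {
      case '=': case 'X': case 'M':
        for (int j = 0; j < o.len; ++j) {
          bool match = (o.op == '=');
          ca += 1; ma += match;
          if (t + j < n && !inrun[t + j]) { co += 1; mo += match; }
        }
        t += o.len;
        break;
      case 'D':
        for (int j = 0; j < o.len; ++j) {
          ca += 1;
          if (t + j < n && !inrun[t + j]) co += 1;
        }
        t += o.len;
        break;
      case 'I': {
        ca += o.len;
        bool near_run = (t - 1 >= 0 && t - 1 < n && inrun[t - 1]) ||
                        (t >= 0 && t < n && inrun[t]);
        if (!near_run) co += o.len;
        break;
      }
      }
    }
    out(a, 0) = ca; out(a, 1) = ma; out(a, 2) = co; out(a, 3) = mo;
  }
  return out;
}
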
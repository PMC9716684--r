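#ifndef NANOMAG_COMMON_H
#define NANOMAG_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// 2-bit base encoding; -1 for anything that is not ACGT (upper case).
inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  case 'N': return 'N';
  case 'n': return 'n';
  default:  return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

struct CigarOp {
  char op;
  int len;
};

// Parse a CIGAR string over ops {=, X, I, D, M}. Throws on anything else.
inline std::vector<CigarOp> parse_cigar(const std::string& cg) {
  std::vector<CigarOp> ops;
  long len = 0;
  for (char c : cg) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
      if (len > 2000000000L) Rcpp::stop("CIGAR op length overflow");
    } else if (c == '=' || c == 'X' || c == 'I' || c == 'D' || c == 'M') {
      if (len <= 0) Rcpp::stop("CIGAR op with non-positive length");
      ops.push_back({c, (int)len});
      len = 0;
    } else {
      Rcpp::stop("unsupported CIGAR op '%s'", std::string(1, c).c_str());
    }
  }
  if (len != 0) Rcpp::stop("trailing length in CIGAR");
  return ops;
}

#endif
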
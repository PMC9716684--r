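#include "common.h"
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  return out;
}

// Overlapping occurrence count of `pattern` across subjects.
// [[Rcpp::export]]
int cpp_count_occ(CharacterVector subjects, std::string pattern) {
  int total = 0;
  if (pattern.empty()) stop("empty pattern");
  for (int i = 0; i < subjects.size(); ++i) {
    std::string s = as<std::string>(subjects[i]);
    size_t pos = s.find(pattern, 0);
    while (pos != std::string::npos) {
      ++total;
      pos = s.find(pattern, pos + 1);
    }
  }
  return total;
}
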
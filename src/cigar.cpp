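#include "common.h"
using namespace Rcpp;

// Per-CIGAR op tallies used all over the package.
// Columns: n_eq, n_x, n_i, n_d, n_m, i_events, d_events, qspan, tspan
// qspan = query-consuming length (=,X,I,M); tspan = target-consuming (=,X,D,M).
// [[Rcpp::export]]
IntegerMatrix cpp_cigar_stats(CharacterVector cigars) {
  int n = cigars.size();
  IntegerMatrix out(n, 9);
  colnames(out) = CharacterVector::create(
    "n_eq", "n_x", "n_i", "n_d", "n_m", "i_events", "d_events", "qspan", "tspan");
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(cigars[i])) {
      for (int j = 0; j < 9; ++j) out(i, j) = NA_INTEGER;
      continue;
    }
    std::vector<CigarOp> ops = parse_cigar(as<std::string>(cigars[i]));
    long eq = 0, x = 0, ins = 0, del = 0, m = 0, ie = 0, de = 0;
    for (const CigarOp& o : ops) {
      switch (o.op) {
      case '=': eq += o.len; break;
      case 'X': x += o.len; break;
      case 'I': ins += o.len; ++ie; break;
      case 'D': del += o.len; ++de; break;
      case 'M': m += o.len; break;
      }
    }
    out(i, 0) = (int)eq; out(i, 1) = (int)x; out(i, 2) = (int)ins;
    out(i, 3) = (int)del; out(i, 4) = (int)m;
    out(i, 5) = (int)ie; out(i, 6) = (int)de;
    out(i, 7) = (int)(eq + x + ins + m);
    out(i, 8) = (int)(eq + x + del + m);
  }
  return out;
}

// Validate one alignment against its sequences.  `qseq` must already be
// oriented (reverse-complemented for '-' alignments) and `qoffset` is the
// 0-based position in qseq where the walk starts.  Returns "" when
// consistent, else a short diagnostic.
// [[Rcpp::export]]
String cpp_check_alignment(std::string target, std::string qseq,
                           int tstart, int qoffset, std::string cigar) {
  std::vector<CigarOp> ops;
  try {
    ops = parse_cigar(cigar);
  } catch (std::exception& e) {
    return String(e.what());
  }
  long t = tstart, q = qoffset;
  long tn = (long)target.size(), qn = (long)qseq.size();
  for (const CigarOp& o : ops) {
    switch (o.op) {
    case '=':
    case 'X':
    case 'M':
      if (t + o.len > tn) return String("walks off target end");
      if (q + o.len > qn) return String("walks off query end");
      if (o.op != 'M') {
        for (int j = 0; j < o.len; ++j) {
          char tb = toupper(target[t + j]), qb = toupper(qseq[q + j]);
          bool same = (tb == qb) && tb != 'N';
          if (o.op == '=' && !same) return String("'=' op over mismatching bases");
          if (o.op == 'X' && same) return String("'X' op over matching bases");
        }
      }
      t += o.len; q += o.len;
      break;
    case 'I':
      if (q + o.len > qn) return String("walks off query end");
      q += o.len;
      break;
    case 'D':
      if (t + o.len > tn) return String("walks off target end");
      t += o.len;
      break;
    }
  }
  return String("");
}

// Resolve M ops into =/X runs using the sequences (same orientation rules
// as cpp_check_alignment).  Returns the resolved CIGAR string.
// [[Rcpp::export]]
String cpp_resolve_m(std::string target, std::string qseq,
                     int tstart, int qoffset, std::string cigar) {
  std::vector<CigarOp> ops = parse_cigar(cigar);
  std::string out;
  out.reserve(cigar.size() * 2);
  long t = tstart, q = qoffset;
  char cur = 0; long curlen = 0;
  auto flush = [&]() {
    if (curlen > 0) { out += std::to_string(curlen); out += cur; }
    cur = 0; curlen = 0;
  };
  auto push = [&](char op, long len) {
    if (op == cur) curlen += len;
    else { flush(); cur = op; curlen = len; }
  };
  for (const CigarOp& o : ops) {
    if (o.op == 'M') {
      if (t + o.len > (long)target.size() || q + o.len > (long)qseq.size())
        stop("CIGAR walks off sequence end while resolving M");
      for (int j = 0; j < o.len; ++j) {
        char tb = toupper(target[t + j]), qb = toupper(qseq[q + j]);
        push((tb == qb && tb != 'N') ? '=' : 'X', 1);
      }
      t += o.len; q += o.len;
    } else {
      push(o.op, o.len);
      if (o.op == 'I') q += o.len;
      else if (o.op == 'D') t += o.len;
      else { t += o.len; q += o.len; }
    }
  }
  flush();
  return String(out);
}
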
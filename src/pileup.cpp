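#include "common.h"
#include <algorithm>
#include <map>
using namespace Rcpp;

// Build a pileup over one contig.  Query sequences must be oriented
// (reverse-complemented for '-' alignments); qoffset is the 0-based start
// of the walk within the oriented query.  Alignments that would walk off
// either sequence are skipped and counted.
// [[Rcpp::export]]
List cpp_build_pileup(std::string contig, IntegerVector tstart,
                      CharacterVector cigar, CharacterVector qseq,
                      IntegerVector qoffset) {
  const long n = (long)contig.size();
  IntegerMatrix counts(n, 4);
  colnames(counts) = CharacterVector::create("A", "C", "G", "T");
  IntegerVector del(n), span(n), jspan(n);
  std::map<std::pair<long, std::string>, int> ins;
  int skipped = 0;

  for (int a = 0; a < tstart.size(); ++a) {
    std::string q = as<std::string>(qseq[a]);
    for (auto& c : q) c = toupper(c);
    std::vector<CigarOp> ops;
    try {
      ops = parse_cigar(as<std::string>(cigar[a]));
    } catch (std::exception& e) {
      ++skipped; continue;
    }
    // pre-validate bounds
    long t = tstart[a], qq = qoffset[a];
    bool ok = t >= 0 && qq >= 0;
    for (const CigarOp& o : ops) {
      if (o.op == '=' || o.op == 'X' || o.op == 'M') { t += o.len; qq += o.len; }
      else if (o.op == 'I') qq += o.len;
      else t += o.len;
    }
    if (!ok || t > n || qq > (long)q.size()) { ++skipped; continue; }

    t = tstart[a]; qq = qoffset[a];
    long t0 = t;
    for (const CigarOp& o : ops) {
      switch (o.op) {
      case '=': case 'X': case 'M':
        for (int j = 0; j < o.len; ++j) {
          int c = base2code(q[qq + j]);
          if (c >= 0) counts(t + j, c)++;   // N never votes
          span[t + j]++;
        }
        t += o.len; qq += o.len;
        break;
      case 'D':
        for (int j = 0; j < o.len; ++j) { del[t + j]++; span[t + j]++; }
        t += o.len;
        break;
      case 'I': {
        long jpos = t - 1;                   // junction after previous column
        if (jpos >= 0)
          ins[{jpos, q.substr(qq, o.len)}]++;
        qq += o.len;
        break;
      }
      }
    }
    // junction after p is crossed by this read for p in [t0, tend-2]
    for (long p = t0; p <= t - 2; ++p) jspan[p]++;
  }

  std::vector<double> ipos; std::vector<std::string> iseq; std::vector<int> icnt;
  for (auto& kv : ins) {
    ipos.push_back((double)kv.first.first);
    iseq.push_back(kv.first.second);
    icnt.push_back(kv.second);
  }
  return List::create(
    _["counts"] = counts, _["del"] = del, _["span"] = span,
    _["junction_span"] = jspan,
    _["insertions"] = DataFrame::create(
      _["pos"] = wrap(ipos), _["seq"] = wrap(iseq), _["count"] = wrap(icnt),
      _["stringsAsFactors"] = false),
    _["skipped"] = skipped);
}

// Observed homopolymer lengths.  For every maximal reference run (length
// >= min_run) fully inside an alignment with at least one aligned flank
// column on each side, tally the observed length: query bases equal to the
// run base aligned over the run's columns, plus pure-base insertions at the
// run's internal and two boundary junctions.  One row per (run, alignment).
// [[Rcpp::export]]
DataFrame cpp_hp_observed(std::string ref, IntegerVector tstart,
                          CharacterVector cigar, CharacterVector qseq,
                          IntegerVector qoffset, int min_run) {
  const long n = (long)ref.size();
  for (auto& c : ref) c = toupper(c);
  // maximal runs
  std::vector<long> rstart, rend;
  std::vector<char> rbase;
  std::vector<int> runid(n, -1);
  long i = 0;
  while (i < n) {
    long j = i + 1;
    while (j < n && ref[j] == ref[i]) ++j;
    if (j - i >= min_run && base2code(ref[i]) >= 0) {
      int id = (int)rstart.size();
      rstart.push_back(i); rend.push_back(j); rbase.push_back(ref[i]);
      for (long p = i; p < j; ++p) runid[p] = id;
    }
    i = j;
  }
  const int nrun = (int)rstart.size();
  std::vector<int> matched(nrun, 0), inserted(nrun, 0);

  std::vector<std::string> o_base;
  std::vector<int> o_true, o_obs;

  for (int a = 0; a < tstart.size(); ++a) {
    std::string q = as<std::string>(qseq[a]);
    for (auto& c : q) c = toupper(c);
    std::vector<CigarOp> ops = parse_cigar(as<std::string>(cigar[a]));
    std::vector<int> touched;
    long t = tstart[a], qq = qoffset[a];
    for (const CigarOp& o : ops) {
      switch (o.op) {
      case '=': case 'X': case 'M':
        for (int j = 0; j < o.len; ++j) {
          int rid = runid[t + j];
          if (rid >= 0 && q[qq + j] == rbase[rid]) {
            if (matched[rid] == 0 && inserted[rid] == 0) touched.push_back(rid);
            matched[rid]++;
          }
        }
        t += o.len; qq += o.len;
        break;
      case 'D':
        t += o.len;
        break;
      case 'I': {
        long p = t - 1;  // junction after column p
        char b = q[qq];
        bool pure = base2code(b) >= 0;
        for (int j = 1; j < o.len && pure; ++j) pure = (q[qq + j] == b);
        if (pure) {
          int rid = -1;
          if (p >= 0 && runid[p] >= 0 && rbase[runid[p]] == b) rid = runid[p];
          else if (p + 1 < n && runid[p + 1] >= 0 && rbase[runid[p + 1]] == b)
            rid = runid[p + 1];
          if (rid >= 0) {
            if (matched[rid] == 0 && inserted[rid] == 0) touched.push_back(rid);
            inserted[rid] += o.len;
          }
        }
        qq += o.len;
        break;
      }
      }
    }
    long tend = t;
    // emit every run fully inside the alignment, including obs == 0 runs
    int rid0 = (int)(std::lower_bound(rstart.begin(), rstart.end(),
                                      (long)tstart[a] + 1) - rstart.begin());
    for (int rid = rid0; rid < nrun && rend[rid] <= tend - 1; ++rid) {
      o_base.push_back(std::string(1, rbase[rid]));
      o_true.push_back((int)(rend[rid] - rstart[rid]));
      o_obs.push_back(matched[rid] + inserted[rid]);
    }
    for (int rid : touched) { matched[rid] = 0; inserted[rid] = 0; }
  }
  return DataFrame::create(
    _["base"] = wrap(o_base), _["true_len"] = wrap(o_true),
    _["obs_len"] = wrap(o_obs), _["stringsAsFactors"] = false);
}
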
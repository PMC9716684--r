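#include "common.h"
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// k-mer index over the forward strand of the targets.  Reverse-strand hits
// are found by looking up the reverse complement of query k-mers, which is
// equivalent to indexing both strands.
struct KmerIndexCpp {
  int k;
  int w;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  // kmer -> packed hits (tid << 40 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> tab;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int k, int w) {
  XPtr<KmerIndexCpp> xp(new KmerIndexCpp(), true);
  xp->k = k;
  xp->w = w;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < ids.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    for (auto& c : s) c = toupper(c);
    xp->ids.push_back(as<std::string>(ids[t]));
    xp->seqs.push_back(s);
    if ((int)s.size() < k) continue;  // caller warns
    uint64_t val = 0;
    int valid = 0;
    for (size_t pos = 0; pos < s.size(); ++pos) {
      int c = base2code(s[pos]);
      if (c < 0) { valid = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        uint64_t start = pos - (uint64_t)k + 1;
        if (start % (uint64_t)w == 0)
          xp->tab[val].push_back(((uint64_t)t << 40) | start);
      }
    }
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xpsexp) {
  XPtr<KmerIndexCpp> xp(xpsexp);
  size_t nk = xp->tab.size(), nh = 0;
  for (auto& kv : xp->tab) nh += kv.second.size();
  return List::create(_["k"] = xp->k, _["w"] = xp->w,
                      _["target_ids"] = wrap(xp->ids),
                      _["n_kmers"] = (double)nk, _["n_positions"] = (double)nh);
}

namespace {

struct Seed { int qpos; long tpos; };

struct Chain {
  int tid;
  char strand;
  int q_first, q_last;
  long t_first, t_last;
  int n_seeds;
};

struct AlnOut {
  int tid;
  char strand;
  long tstart, tend;
  std::string cigar;
  long n_eq, n_cols;
};

// Banded "fitting" alignment: the whole oriented query against a target
// window with free end gaps on the target side.  Unit costs.  diag0 is the
// expected target offset of query position 0 within the window.
bool banded_fit(const std::string& q, const std::string& win,
                long diag0, int band, AlnOut& out) {
  const long n = (long)q.size(), wlen = (long)win.size();
  const int W = 2 * band + 1;
  const int INF = 1 << 28;
  if ((double)(n + 1) * W > 1.6e9)
    stop("alignment band too large; reduce band_fraction");
  // P/C are sentinel-padded: raw band index u maps to P[u + 1].
  std::vector<int> P(W + 2, INF), C(W + 2, INF);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 3);  // 0 diag, 1 up(I), 2 left(D)
  auto jlo = [&](long i) { return std::max(0L, i + diag0 - band); };
  auto jhi = [&](long i) { return std::min(wlen, i + diag0 + band); };
  if (jlo(0) > jhi(0)) return false;
  // row 0: free leading target gap
  for (long j = jlo(0); j <= jhi(0); ++j) P[j - (diag0 - band) + 1] = 0;
  const char* wc = win.c_str();
  for (long i = 1; i <= n; ++i) {
    long off = i + diag0 - band;      // window col at raw band index 0
    long lo = jlo(i), hi = jhi(i);
    if (lo > hi) return false;
    std::fill(C.begin(), C.end(), INF);
    const char qc = q[i - 1];
    uint8_t* tbrow = &tb[(size_t)i * W];
    long j = lo;
    if (j == 0) {  // column 0: only a query-consuming move is possible
      int u = (int)(j - off);
      int v = P[u + 2] + 1;             // prev row, same j
      C[u + 1] = v; tbrow[u] = 1;
      ++j;
    }
    for (; j <= hi; ++j) {
      int u = (int)(j - off);
      // prev-row raw index for same j is u+1 (offsets shift by one per row)
      int diagv = P[u + 1] + ((qc != wc[j - 1]) | (qc == 'N'));
      int insv = P[u + 2] + 1;
      int leftv = C[u] + 1;
      int best = diagv; uint8_t code = 0;
      if (insv < best) { best = insv; code = 1; }
      if (leftv < best) { best = leftv; code = 2; }
      C[u + 1] = best;
      tbrow[u] = code;
    }
    std::swap(P, C);
  }
  // best end in final row (free trailing target gap); prefer smaller j on ties
  long off_n = n + diag0 - band;
  long lo = jlo(n), hi = jhi(n);
  int best = INF; long jend = -1;
  for (long j = lo; j <= hi; ++j) {
    int v = P[j - off_n + 1];
    if (v < best) { best = v; jend = j; }
  }
  if (jend < 0 || best >= INF) return false;
  // traceback
  std::string ops;
  long i = n, j = jend;
  while (i > 0) {
    long off = i + diag0 - band;
    uint8_t code = tb[(size_t)i * W + (j - off)];
    if (code == 0) {
      char tc = win[j - 1];
      bool match = (q[i - 1] == tc) && q[i - 1] != 'N';
      ops.push_back(match ? '=' : 'X');
      --i; --j;
    } else if (code == 1) {
      ops.push_back('I');
      --i;
    } else if (code == 2) {
      ops.push_back('D');
      --j;
    } else {
      return false;  // fell out of band
    }
  }
  std::reverse(ops.begin(), ops.end());
  // strip leading/trailing D (they belong to the free target gaps)
  size_t b0 = 0, b1 = ops.size();
  long tstart = j;
  while (b0 < b1 && ops[b0] == 'D') { ++b0; ++tstart; }
  while (b1 > b0 && ops[b1 - 1] == 'D') --b1;
  long tend = tstart;
  std::string cg;
  long eq = 0, cols = 0;
  char curop = 0; long curlen = 0;
  auto flush = [&]() {
    if (curlen > 0) { cg += std::to_string(curlen); cg += curop; }
    curop = 0; curlen = 0;
  };
  for (size_t p = b0; p < b1; ++p) {
    char o = ops[p];
    if (o == '=' ) ++eq;
    ++cols;
    if (o == '=' || o == 'X' || o == 'D') ++tend;
    if (o == curop) ++curlen; else { flush(); curop = o; curlen = 1; }
  }
  flush();
  out.tstart = tstart; out.tend = tend;
  out.cigar = cg; out.n_eq = eq; out.n_cols = cols;
  return true;
}

}  // namespace

// Map oriented reads against the index.  Returns one row per chained-and-
// extended candidate, unsorted; R orders and filters.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xpsexp, CharacterVector read_ids,
                        CharacterVector read_seqs, double band_fraction,
                        int min_chain_seeds, int max_occ) {
  XPtr<KmerIndexCpp> xp(xpsexp);
  const int k = xp->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<std::string> o_rid, o_tid, o_cigar;
  std::vector<char> o_strand;
  std::vector<double> o_qs, o_qe, o_ts, o_te, o_eq, o_cols;

  for (int r = 0; r < read_ids.size(); ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    for (auto& c : fwd) c = toupper(c);
    const long qlen = (long)fwd.size();
    if (qlen < k) continue;
    const int tol = std::max(64, (int)(band_fraction * qlen));
    std::string rc = revcomp(fwd);
    for (int si = 0; si < 2; ++si) {
      char strand = si == 0 ? '+' : '-';
      const std::string& q = si == 0 ? fwd : rc;
      // seeds per target
      std::unordered_map<int, std::vector<Seed>> per_target;
      uint64_t val = 0; int valid = 0;
      for (long pos = 0; pos < qlen; ++pos) {
        int c = base2code(q[pos]);
        if (c < 0) { valid = 0; val = 0; continue; }
        val = ((val << 2) | (uint64_t)c) & mask;
        if (++valid >= k) {
          long qpos = pos - k + 1;
          auto it = xp->tab.find(val);
          if (it == xp->tab.end()) continue;
          if ((int)it->second.size() > max_occ) continue;
          for (uint64_t h : it->second) {
            int tid = (int)(h >> 40);
            long tpos = (long)(h & ((1ULL << 40) - 1));
            per_target[tid].push_back({(int)qpos, tpos});
          }
        }
      }
      // order targets deterministically
      std::vector<int> tids;
      for (auto& kv : per_target) tids.push_back(kv.first);
      std::sort(tids.begin(), tids.end());
      for (int tid : tids) {
        std::vector<Seed>& seeds = per_target[tid];
        // cluster by diagonal
        std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
          long da = a.tpos - a.qpos, db = b.tpos - b.qpos;
          if (da != db) return da < db;
          return a.qpos < b.qpos;
        });
        size_t i0 = 0;
        while (i0 < seeds.size()) {
          size_t i1 = i0 + 1;
          long d0 = seeds[i0].tpos - seeds[i0].qpos;
          while (i1 < seeds.size() &&
                 seeds[i1].tpos - seeds[i1].qpos - d0 <= tol) ++i1;
          if ((int)(i1 - i0) >= min_chain_seeds) {
            // longest colinear subset by (qpos, tpos)
            std::vector<Seed> cl(seeds.begin() + i0, seeds.begin() + i1);
            std::sort(cl.begin(), cl.end(), [](const Seed& a, const Seed& b) {
              if (a.qpos != b.qpos) return a.qpos < b.qpos;
              return a.tpos < b.tpos;
            });
            // LIS on tpos (strictly increasing)
            std::vector<long> tails;
            std::vector<int> tailidx, parent(cl.size(), -1), tailpos;
            for (size_t s = 0; s < cl.size(); ++s) {
              long v = cl[s].tpos;
              size_t lo = std::lower_bound(tails.begin(), tails.end(), v) - tails.begin();
              if (lo == tails.size()) { tails.push_back(v); tailidx.push_back((int)s); }
              else { tails[lo] = v; tailidx[lo] = (int)s; }
              parent[s] = lo > 0 ? tailidx[lo - 1] : -1;
            }
            int chain_len = (int)tails.size();
            if (chain_len >= min_chain_seeds) {
              int last = tailidx[chain_len - 1], first = last;
              long dmin = cl[last].tpos - cl[last].qpos, dmax = dmin;
              while (parent[first] >= 0) {
                first = parent[first];
                long d = cl[first].tpos - cl[first].qpos;
                dmin = std::min(dmin, d);
                dmax = std::max(dmax, d);
              }
              const std::string& tseq = xp->seqs[tid];
              long tlen = (long)tseq.size();
              long t_first = cl[first].tpos, q_first = cl[first].qpos;
              long t_last = cl[last].tpos, q_last = cl[last].qpos;
              // DP band: the chain's observed diagonal drift plus slack,
              // never wider than the chaining tolerance
              int band = (int)std::min(
                (long)tol,
                std::max(64L, (dmax - dmin) + 64 + qlen / 50));
              long pad = band;
              long t_from = std::max(0L, t_first - q_first - pad);
              long t_to = std::min(tlen, t_last + k + (qlen - q_last - k) + pad);
              if (t_to > t_from) {
                long diag0 = (t_first - q_first) - t_from;
                AlnOut a;
                if (banded_fit(q, tseq.substr(t_from, t_to - t_from),
                               diag0, band, a) && a.n_cols > 0) {
                  o_rid.push_back(as<std::string>(read_ids[r]));
                  o_tid.push_back(xp->ids[tid]);
                  o_strand.push_back(strand);
                  o_qs.push_back(0);
                  o_qe.push_back((double)qlen);
                  o_ts.push_back((double)(t_from + a.tstart));
                  o_te.push_back((double)(t_from + a.tend));
                  o_cigar.push_back(a.cigar);
                  o_eq.push_back((double)a.n_eq);
                  o_cols.push_back((double)a.n_cols);
                }
              }
            }
          }
          i0 = i1;
        }
      }
    }
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = std::string(1, o_strand[i]);
  return DataFrame::create(
    _["query_id"] = wrap(o_rid), _["target_id"] = wrap(o_tid),
    _["strand"] = strand,
    _["query_start"] = wrap(o_qs), _["query_end"] = wrap(o_qe),
    _["target_start"] = wrap(o_ts), _["target_end"] = wrap(o_te),
    _["cigar"] = wrap(o_cigar), _["n_match"] = wrap(o_eq),
    _["n_cols"] = wrap(o_cols),
    _["stringsAsFactors"] = false);
}
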
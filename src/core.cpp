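#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Suffix array construction (prefix doubling, O(n log^2 n)).
// Texts are plain byte strings; the sentinel separating concatenated
// sequences is any byte outside {A,C,G,T,N} and needs no special handling
// here because it simply participates in the lexicographic order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(std::string text) {
  const int n = (int) text.size();
  if (n < 1) stop("empty text");
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = (unsigned char) text[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// Narrow the suffix-array interval [lo,hi) (all suffixes sharing a prefix of
// length d with q) to the sub-interval matching q[d] at offset d.  Suffixes
// shorter than d+1 sort first inside the interval.
static inline void narrow(const std::string& t, const int* sa,
                          int& lo, int& hi, int d, unsigned char c) {
  const int n = (int) t.size();
  int a = lo, b = hi;
  // lower bound: first suffix with char_at(d) >= c
  while (a < b) {
    int m = (a + b) / 2;
    int p = sa[m] + d;
    int ch = p < n ? (unsigned char) t[p] : -1;
    if (ch < (int) c) a = m + 1; else b = m;
  }
  int new_lo = a;
  b = hi;
  // upper bound: first suffix with char_at(d) > c
  while (a < b) {
    int m = (a + b) / 2;
    int p = sa[m] + d;
    int ch = p < n ? (unsigned char) t[p] : -1;
    if (ch <= (int) c) a = m + 1; else b = m;
  }
  lo = new_lo; hi = a;
}

// COUNTLCP: count and length of the longest prefix of q present in the text,
// plus the matching suffix-array interval at every prefix depth.
static int count_lcp_core(const std::string& t, const int* sa, int n,
                          const std::string& q,
                          std::vector<int>& los, std::vector<int>& his) {
  int lo = 0, hi = n, d = 0;
  const int ql = (int) q.size();
  los.clear(); his.clear();
  while (d < ql) {
    int nlo = lo, nhi = hi;
    narrow(t, sa, nlo, nhi, d, (unsigned char) q[d]);
    if (nlo >= nhi) break;
    lo = nlo; hi = nhi; ++d;
    los.push_back(lo); his.push_back(hi);
  }
  return d; // lcp length; interval at depth d is (los[d-1], his[d-1])
}

// [[Rcpp::export]]
List sa_count_lcp_cpp(std::string text, IntegerVector sa, std::string q,
                      double max_hits) {
  const int n = (int) text.size();
  std::vector<int> los, his;
  int l = count_lcp_core(text, sa.begin(), n, q, los, his);
  if (l == 0)
    return List::create(_["count"] = 0, _["lcp"] = 0,
                        _["hits"] = IntegerVector(0));
  int lo = los[l - 1], hi = his[l - 1];
  int c = hi - lo;
  IntegerVector hits(0);
  if ((double) c <= max_hits) {
    hits = IntegerVector(c);
    for (int i = 0; i < c; ++i) hits[i] = sa[lo + i];
    std::sort(hits.begin(), hits.end());
  }
  return List::create(_["count"] = c, _["lcp"] = l, _["hits"] = hits);
}

// Anchor scan: at every read position take the LCP with the text, shorten it
// by `shorten` (never below K), and emit one anchor per located text
// position.  Positions whose (shortened) match occurs more than max_count
// times, or whose match is shorter than K or contains a non-ACGT base,
// contribute nothing.
// [[Rcpp::export]]
IntegerMatrix scan_anchors_cpp(std::string text, IntegerVector sa,
                               std::string read, int K, int shorten,
                               double max_count) {
  const int n = (int) text.size();
  const int R = (int) read.size();
  std::vector<int> out; // triples+freq flattened
  std::vector<int> los, his;
  for (int i = 0; i + K <= R; ++i) {
    std::string suf = read.substr(i);
    int l = count_lcp_core(text, sa.begin(), n, suf, los, his);
    if (l < K) continue;
    int el = l - shorten; if (el < K) el = K;
    bool bad = false;
    for (int p = i; p < i + el; ++p) {
      char ch = read[p];
      if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') { bad = true; break; }
    }
    if (bad) continue;
    int lo = los[el - 1], hi = his[el - 1];
    int c = hi - lo;
    if ((double) c > max_count) continue;
    for (int m = lo; m < hi; ++m) {
      out.push_back(i); out.push_back(sa[m]); out.push_back(el); out.push_back(c);
    }
  }
  const int na = (int) out.size() / 4;
  IntegerMatrix res(na, 4);
  for (int a = 0; a < na; ++a)
    for (int f = 0; f < 4; ++f) res(a, f) = out[4 * a + f];
  colnames(res) = CharacterVector::create("read_pos", "text_pos", "length", "freq");
  return res;
}

// ---------------------------------------------------------------------------
// Banded alignment.  Global in the read, free end gaps on the interval.
// Costs are phred scaled; with quality tracks the moves are
//   diagonal:   0 if r_i = g_j, S_i if the alternative call matches g_j,
//               MISMATCHPRIOR otherwise
//   vertical:   I_i               (an inserted read base)
//   horizontal: D_i if the alternative deleted call matches the preceding
//               interval base, DELETIONPRIOR otherwise
// without tracks, flat penalties substitute.  Traceback prefers diagonal,
// then deletion, then insertion on ties.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List banded_dp_cpp(std::string r, std::string g,
                   IntegerVector lo, IntegerVector hi,
                   NumericVector qi, NumericVector qs, NumericVector qd,
                   std::string shat, std::string dhat, bool has_qv,
                   double mismatch_prior, double deletion_prior,
                   double flat_ins, double flat_del, double flat_mismatch) {
  const int R = (int) r.size();
  const int Lc = (int) g.size();
  const double INF = 1e18;
  if ((double)(R + 1) * (double)(Lc + 1) > 8e7) stop("alignment grid too large");
  std::vector<double> cost((size_t)(R + 1) * (Lc + 1), INF);
  std::vector<unsigned char> mv((size_t)(R + 1) * (Lc + 1), 0); // 1=diag 2=del 3=ins
  auto at = [Lc](int i, int j) { return (size_t) i * (Lc + 1) + j; };
  for (int j = 0; j <= Lc; ++j) cost[at(0, j)] = 0.0; // free leading interval
  for (int i = 1; i <= R; ++i) {
    int jlo = lo[i - 1], jhi = hi[i - 1];
    if (jlo < 0) jlo = 0;
    if (jhi > Lc) jhi = Lc;
    for (int j = jlo; j <= jhi; ++j) {
      double best = INF; unsigned char m = 0;
      if (j >= 1 && cost[at(i - 1, j - 1)] < INF) {
        double d;
        if (r[i - 1] == g[j - 1]) d = 0.0;
        else if (has_qv && shat[i - 1] == g[j - 1]) d = qs[i - 1];
        else d = has_qv ? mismatch_prior : flat_mismatch;
        double v = cost[at(i - 1, j - 1)] + d;
        if (v < best) { best = v; m = 1; }
      }
      if (j >= 1 && cost[at(i, j - 1)] < INF) {
        double d;
        if (has_qv) d = (j >= 2 && dhat[i - 1] == g[j - 2]) ? qd[i - 1] : deletion_prior;
        else d = flat_del;
        double v = cost[at(i, j - 1)] + d;
        if (v < best) { best = v; m = 2; }
      }
      if (cost[at(i - 1, j)] < INF) {
        double v = cost[at(i - 1, j)] + (has_qv ? qi[i - 1] : flat_ins);
        if (v < best) { best = v; m = 3; }
      }
      cost[at(i, j)] = best; mv[at(i, j)] = m;
    }
  }
  // free trailing interval: best cell anywhere in the last row
  double best = INF; int jend = -1;
  for (int j = 0; j <= Lc; ++j)
    if (cost[at(R, j)] < best) { best = cost[at(R, j)]; jend = j; }
  if (jend < 0 || best >= INF)
    return List::create(_["ok"] = false);
  // traceback
  std::vector<char> ops;
  int i = R, j = jend;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  while (i > 0) {
    unsigned char m = mv[at(i, j)];
    if (m == 1) {
      ops.push_back('M');
      if (r[i - 1] == g[j - 1]) ++nmatch; else ++nmis;
      --i; --j;
    } else if (m == 2) {
      ops.push_back('D'); ++ndel; --j;
    } else if (m == 3) {
      ops.push_back('I'); ++nins; --i;
    } else {
      return List::create(_["ok"] = false);
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode into CIGAR
  std::string cigar;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q2 = p;
    while (q2 < ops.size() && ops[q2] == ops[p]) ++q2;
    cigar += std::to_string(q2 - p); cigar += ops[p];
    p = q2;
  }
  if (ops.empty()) cigar = "*";
  return List::create(_["ok"] = true, _["cost"] = best, _["cigar"] = cigar,
                      _["g_start"] = j, _["g_end"] = jend,
                      _["n_match"] = nmatch, _["n_mismatch"] = nmis,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}
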
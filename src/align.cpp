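// Seed-and-extend local nucleotide alignment engine, plus small helpers
// (Smith-Waterman peptide alignment, k-mer depth, Markov sequence sampling)
// shared by the mapping, recruitment and binning layers.
//
// Scoring (nucleotide): match +1, mismatch -2, gap open 5, gap extend 2
// (costs subtracted). Identity = matches / alignment columns, gaps counted
// as columns. Coordinates are 0-based half-open on the forward strand of
// both sequences; strand '-' means the reverse complement of the query
// aligns to the subject.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

const int NT_MATCH = 1;
const int NT_MISMATCH = -2;
const int NT_GAP_OPEN = 5;   // cost of opening (first gap column costs open+ext)
const int NT_GAP_EXT = 2;
const int DIAG_BAND = 64;    // anchors within this diagonal drift share a cluster
const int CHAIN_MAX_GAP = 400;   // larger anchor gaps split the chain
const int EXT_BAND = 24;
const int EXT_XDROP = 40;
const int EXT_CAP = 2000;
const int EXT_GAP = 7;       // linear gap cost inside terminal extensions
const long NW_MAX_CELLS = 250000;
const long NEG_INF = -1000000000L;

inline int basecode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char compbase(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compbase(r[i]);
  return r;
}

// ---------------------------------------------------------------- index

// flat sorted index: entries pack kmer (30 bits) and a global position
// (34 bits) over the concatenated reference set
struct Index {
  int k;
  uint32_t mask;
  int max_occ;
  std::vector<uint64_t> entries;
  std::vector<uint64_t> offsets;  // global start of each reference

  void build(const std::vector<std::string>& refs, int k_, int max_occ_) {
    k = k_;
    max_occ = max_occ_;
    mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    uint64_t total = 0;
    offsets.resize(refs.size());
    for (size_t r = 0; r < refs.size(); ++r) {
      offsets[r] = total;
      total += refs[r].size();
    }
    entries.reserve((size_t)total);
    for (size_t r = 0; r < refs.size(); ++r) {
      const std::string& s = refs[r];
      uint32_t val = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = basecode(s[i]);
        if (c < 0) { run = 0; val = 0; continue; }
        val = ((val << 2) | (uint32_t)c) & mask;
        if (++run >= k) {
          uint64_t gpos = offsets[r] + (i - k + 1);
          entries.push_back(((uint64_t)val << 34) | gpos);
        }
      }
    }
    std::sort(entries.begin(), entries.end());
  }

  // [first, last) range of entries for a k-mer; empty when over max_occ
  std::pair<const uint64_t*, const uint64_t*> lookup(uint32_t val) const {
    uint64_t lo = (uint64_t)val << 34, hi = ((uint64_t)val + 1) << 34;
    const uint64_t* a = std::lower_bound(entries.data(),
                                         entries.data() + entries.size(), lo);
    const uint64_t* b = a;
    const uint64_t* end = entries.data() + entries.size();
    int n = 0;
    while (b < end && *b < hi) {
      if (++n > max_occ) return {a, a};
      ++b;
    }
    return {a, b};
  }

  int ref_of(uint64_t gpos) const {
    return (int)(std::upper_bound(offsets.begin(), offsets.end(), gpos) -
                 offsets.begin()) - 1;
  }
};

struct Anchor { int ref; long diag; int q; int s; };

struct Hit {
  int ref;
  int qstart, qend, sstart, send;
  char strand;
  long matches, cols, score;
};

// -------------------------------------------- global affine gap alignment

// Aligns two short segments globally; accumulates matches / columns / score.
void nw_affine(const std::string& A, int a0, int a1,
               const std::string& B, int b0, int b1,
               long& matches, long& cols, long& score) {
  int na = a1 - a0, nb = b1 - b0;
  if (na == 0 && nb == 0) return;
  if (na == 0 || nb == 0) {
    int g = na + nb;
    cols += g;
    score -= (long)NT_GAP_OPEN + (long)NT_GAP_EXT * g;
    return;
  }
  if ((long)na * (long)nb > NW_MAX_CELLS) {
    // degenerate huge gap between anchors: score it as a mismatch block
    int mn = std::min(na, nb), mx = std::max(na, nb);
    cols += mx;
    score += (long)NT_MISMATCH * mn;
    if (mx > mn) score -= (long)NT_GAP_OPEN + (long)NT_GAP_EXT * (mx - mn);
    return;
  }
  int W = nb + 1;
  std::vector<long> M((na + 1) * W, NEG_INF), X((na + 1) * W, NEG_INF),
      Y((na + 1) * W, NEG_INF);
  std::vector<char> tbM((na + 1) * W, 0), tbX((na + 1) * W, 0),
      tbY((na + 1) * W, 0);
  M[0] = 0;
  for (int i = 1; i <= na; ++i) {
    X[i * W] = -(long)NT_GAP_OPEN - (long)NT_GAP_EXT * i;
    tbX[i * W] = (i == 1) ? 'M' : 'X';
  }
  for (int j = 1; j <= nb; ++j) {
    Y[j] = -(long)NT_GAP_OPEN - (long)NT_GAP_EXT * j;
    tbY[j] = (j == 1) ? 'M' : 'Y';
  }
  for (int i = 1; i <= na; ++i) {
    int ca = basecode(A[a0 + i - 1]);
    for (int j = 1; j <= nb; ++j) {
      int cb = basecode(B[b0 + j - 1]);
      int sub = (ca >= 0 && ca == cb) ? NT_MATCH : NT_MISMATCH;
      long d = M[(i - 1) * W + j - 1], x = X[(i - 1) * W + j - 1],
           y = Y[(i - 1) * W + j - 1];
      long best = d; char tb = 'M';
      if (x > best) { best = x; tb = 'X'; }
      if (y > best) { best = y; tb = 'Y'; }
      M[i * W + j] = (best <= NEG_INF / 2) ? NEG_INF : best + sub;
      tbM[i * W + j] = tb;
      long xo = M[(i - 1) * W + j] - NT_GAP_OPEN - NT_GAP_EXT;
      long xe = X[(i - 1) * W + j] - NT_GAP_EXT;
      if (xo >= xe) { X[i * W + j] = xo; tbX[i * W + j] = 'M'; }
      else { X[i * W + j] = xe; tbX[i * W + j] = 'X'; }
      long yo = M[i * W + j - 1] - NT_GAP_OPEN - NT_GAP_EXT;
      long ye = Y[i * W + j - 1] - NT_GAP_EXT;
      if (yo >= ye) { Y[i * W + j] = yo; tbY[i * W + j] = 'M'; }
      else { Y[i * W + j] = ye; tbY[i * W + j] = 'Y'; }
    }
  }
  long sM = M[na * W + nb], sX = X[na * W + nb], sY = Y[na * W + nb];
  char state = 'M'; long best = sM;
  if (sX > best) { best = sX; state = 'X'; }
  if (sY > best) { best = sY; state = 'Y'; }
  score += best;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    if (i == 0) state = 'Y';
    else if (j == 0) state = 'X';
    if (state == 'M') {
      char prev = tbM[i * W + j];
      int ca = basecode(A[a0 + i - 1]), cb = basecode(B[b0 + j - 1]);
      cols += 1;
      if (ca >= 0 && ca == cb) matches += 1;
      --i; --j;
      state = prev;
      if (i == 0 && j == 0) break;
      if (i == 0 && j > 0) state = 'Y';
      if (j == 0 && i > 0) state = 'X';
    } else if (state == 'X') {
      char prev = tbX[i * W + j];
      cols += 1; --i;
      state = prev;
    } else {
      char prev = tbY[i * W + j];
      cols += 1; --j;
      state = prev;
    }
  }
}

// ------------------------------------------------- banded x-drop extension

// Extends forward from the origin of A against B (both already oriented so
// that the extension direction is increasing index). Local: the extension
// ends at the best-scoring cell. Linear gap cost inside the band.
void extend_fwd(const char* A, int la, const char* B, int lb,
                int& ext_a, int& ext_b, long& matches, long& cols,
                long& score) {
  ext_a = 0; ext_b = 0;
  la = std::min(la, EXT_CAP);
  lb = std::min(lb, EXT_CAP);
  if (la == 0 || lb == 0) return;
  int W = 2 * EXT_BAND + 1;
  int maxrow = std::min(la, lb + EXT_BAND);
  std::vector<long> prev(W, NEG_INF), cur(W, NEG_INF);
  std::vector<char> tb((size_t)(maxrow + 1) * W, 0);
  // row 0: j = d (only d >= 0 valid)
  long best = 0; int best_i = 0, best_d = 0;
  for (int d = 0; d <= EXT_BAND; ++d) {
    int j = d;
    if (j > lb) break;
    prev[d + EXT_BAND] = -(long)EXT_GAP * j;
    tb[(size_t)0 * W + d + EXT_BAND] = 'Y';
  }
  tb[(size_t)0 * W + EXT_BAND] = 0;
  int rows_done = 0;
  for (int i = 1; i <= maxrow; ++i) {
    long rowmax = NEG_INF;
    for (int d = -EXT_BAND; d <= EXT_BAND; ++d) {
      int j = i + d;
      cur[d + EXT_BAND] = NEG_INF;
      if (j < 0 || j > lb) continue;
      long s_diag = NEG_INF, s_up = NEG_INF, s_left = NEG_INF;
      if (j >= 1) s_diag = prev[d + EXT_BAND];              // (i-1, j-1)
      if (d + 1 <= EXT_BAND) s_up = prev[d + 1 + EXT_BAND]; // (i-1, j)
      if (d - 1 >= -EXT_BAND) s_left = cur[d - 1 + EXT_BAND]; // (i, j-1)
      long val = NEG_INF; char mv = 0;
      if (j >= 1 && s_diag > NEG_INF / 2) {
        int ca = basecode(A[i - 1]), cb = basecode(B[j - 1]);
        int sub = (ca >= 0 && ca == cb) ? NT_MATCH : NT_MISMATCH;
        val = s_diag + sub; mv = 'M';
      }
      if (s_up > NEG_INF / 2 && s_up - EXT_GAP > val) { val = s_up - EXT_GAP; mv = 'X'; }
      if (s_left > NEG_INF / 2 && s_left - EXT_GAP > val) { val = s_left - EXT_GAP; mv = 'Y'; }
      if (mv == 0) continue;
      cur[d + EXT_BAND] = val;
      tb[(size_t)i * W + d + EXT_BAND] = mv;
      if (val > rowmax) rowmax = val;
      if (val > best) { best = val; best_i = i; best_d = d; }
    }
    rows_done = i;
    std::swap(prev, cur);
    if (rowmax < best - EXT_XDROP) break;
  }
  (void)rows_done;
  if (best <= 0) return;  // no profitable extension
  // traceback from the best cell
  int i = best_i, d = best_d;
  while (i > 0 || d != 0) {
    char mv = tb[(size_t)i * W + d + EXT_BAND];
    if (mv == 'M') {
      int ca = basecode(A[i - 1]), cb = basecode(B[i + d - 1]);
      cols += 1;
      if (ca >= 0 && ca == cb) matches += 1;
      i -= 1;
    } else if (mv == 'X') {
      cols += 1; i -= 1; d += 1;
    } else if (mv == 'Y') {
      cols += 1; d -= 1;
    } else break;
  }
  ext_a = best_i;
  ext_b = best_i + best_d;
  score += best;
}

// -------------------------------------------------------------- chaining

struct Segment { int qs, qe, ss, se; };

// strictly-increasing LIS over subject positions (anchors pre-sorted by
// (q asc, s desc) so ties in q cannot co-occur in a chain)
std::vector<int> lis_chain(const std::vector<Anchor>& a) {
  int n = (int)a.size();
  std::vector<int> tails;        // indices into a
  std::vector<int> parent(n, -1);
  std::vector<int> tail_idx;
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (a[tails[mid]].s < a[i].s) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) parent[i] = tails[lo - 1];
    if (lo == (int)tails.size()) tails.push_back(i); else tails[lo] = i;
  }
  std::vector<int> chain;
  if (!tails.empty()) {
    int cur = tails.back();
    while (cur >= 0) { chain.push_back(cur); cur = parent[cur]; }
    std::reverse(chain.begin(), chain.end());
  }
  return chain;
}

void align_chain(const std::string& q, const std::string& ref, int refid,
                 char strand, const std::vector<Segment>& segs,
                 double min_id, int min_len, std::vector<Hit>& out) {
  if (segs.empty()) return;
  long matches = 0, cols = 0, score = 0;
  // exact segments
  for (size_t i = 0; i < segs.size(); ++i) {
    int len = segs[i].qe - segs[i].qs;
    matches += len; cols += len; score += (long)NT_MATCH * len;
  }
  // inter-segment gaps
  for (size_t i = 1; i < segs.size(); ++i) {
    nw_affine(q, segs[i - 1].qe, segs[i].qs, ref, segs[i - 1].se, segs[i].ss,
              matches, cols, score);
  }
  int qs = segs.front().qs, qe = segs.back().qe;
  int ss = segs.front().ss, se = segs.back().se;
  // left extension (reverse both prefixes)
  {
    std::string aprefix(q.rbegin() + (q.size() - qs), q.rend());
    std::string bprefix(ref.rbegin() + (ref.size() - ss), ref.rend());
    int ea = 0, eb = 0;
    extend_fwd(aprefix.c_str(), qs, bprefix.c_str(), ss, ea, eb, matches,
               cols, score);
    qs -= ea; ss -= eb;
  }
  // right extension
  {
    int ea = 0, eb = 0;
    extend_fwd(q.c_str() + qe, (int)q.size() - qe, ref.c_str() + se,
               (int)ref.size() - se, ea, eb, matches, cols, score);
    qe += ea; se += eb;
  }
  if (cols <= 0) return;
  double pid = 100.0 * (double)matches / (double)cols;
  if (pid + 1e-9 < min_id || cols < min_len) return;
  Hit h;
  h.ref = refid; h.qstart = qs; h.qend = qe; h.sstart = ss; h.send = se;
  h.strand = strand; h.matches = matches; h.cols = cols; h.score = score;
  out.push_back(h);
}

void process_cluster(const std::string& q, const std::string& ref, int refid,
                     char strand, std::vector<Anchor>& cl, int k,
                     double min_id, int min_len, std::vector<Hit>& out) {
  std::sort(cl.begin(), cl.end(), [](const Anchor& x, const Anchor& y) {
    if (x.q != y.q) return x.q < y.q;
    return x.s > y.s;
  });
  std::vector<int> chain = lis_chain(cl);
  if (chain.empty()) return;
  // break the chain at oversized gaps, merge anchors into exact segments
  std::vector<std::vector<Segment>> pieces;
  std::vector<Segment> segs;
  Segment cur{cl[chain[0]].q, cl[chain[0]].q + k, cl[chain[0]].s,
              cl[chain[0]].s + k};
  for (size_t ci = 1; ci < chain.size(); ++ci) {
    const Anchor& an = cl[chain[ci]];
    long qgap = an.q - (cur.qe);
    long sgap = an.s - (cur.se);
    if (qgap > CHAIN_MAX_GAP || sgap > CHAIN_MAX_GAP) {
      segs.push_back(cur);
      pieces.push_back(segs);
      segs.clear();
      cur = Segment{an.q, an.q + k, an.s, an.s + k};
      continue;
    }
    if ((long)(an.s - an.q) == (long)(cur.ss - cur.qs) && an.q <= cur.qe) {
      // same diagonal, contiguous/overlapping: extend the exact segment
      cur.qe = std::max(cur.qe, an.q + k);
      cur.se = std::max(cur.se, an.s + k);
    } else {
      // new segment; trim any conflict with the previous one
      int nqs = an.q, nss = an.s;
      int trim = 0;
      if (nqs < cur.qe) trim = std::max(trim, cur.qe - nqs);
      if (nss < cur.se) trim = std::max(trim, cur.se - nss);
      nqs += trim; nss += trim;
      if (nqs + 1 > an.q + k || nss + 1 > an.s + k) continue;  // swallowed
      segs.push_back(cur);
      cur = Segment{nqs, an.q + k, nss, an.s + k};
    }
  }
  segs.push_back(cur);
  pieces.push_back(segs);
  // spurious repeat anchors on shifted diagonals create false indels in an
  // otherwise colinear chain: drop short off-diagonal segments sandwiched
  // between colinear neighbours, and short off-diagonal terminal segments
  for (auto& p : pieces) {
    bool changed = true;
    while (changed && p.size() > 1) {
      changed = false;
      auto diag_of = [](const Segment& s) { return (long)s.ss - s.qs; };
      for (size_t j = 0; j < p.size(); ++j) {
        int len = p[j].qe - p[j].qs;
        if (len >= 3 * k) continue;
        bool off = false;
        if (j > 0 && j + 1 < p.size()) {
          off = diag_of(p[j - 1]) == diag_of(p[j + 1]) &&
                diag_of(p[j]) != diag_of(p[j - 1]);
        } else if (j == 0 && p.size() > 1) {
          off = diag_of(p[j]) != diag_of(p[1]);
        } else if (j + 1 == p.size() && p.size() > 1) {
          off = diag_of(p[j]) != diag_of(p[j - 1]);
        }
        if (off) {
          p.erase(p.begin() + j);
          changed = true;
          break;
        }
      }
    }
  }
  for (auto& p : pieces)
    align_chain(q, ref, refid, strand, p, min_id, min_len, out);
}

void map_one(const std::string& q, const std::vector<std::string>& refs,
             const Index& idx, char strand, double min_id, int min_len,
             int min_anchors, int stride, std::vector<Hit>& out) {
  int k = idx.k;
  if ((int)q.size() < k) return;
  std::vector<Anchor> anchors;
  uint32_t val = 0; int run = 0;
  const uint64_t GMASK = ((uint64_t)1 << 34) - 1;
  for (size_t i = 0; i < q.size(); ++i) {
    int c = basecode(q[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint32_t)c) & idx.mask;
    ++run;
    if (run >= k && (long)((i - (k - 1)) % (size_t)stride) == 0) {
      auto range = idx.lookup(val);
      if (range.first != range.second) {
        int qp = (int)i - k + 1;
        for (const uint64_t* p = range.first; p != range.second; ++p) {
          uint64_t gpos = *p & GMASK;
          int r = idx.ref_of(gpos);
          int sp = (int)(gpos - idx.offsets[r]);
          anchors.push_back(Anchor{r, (long)sp - qp, qp, sp});
        }
      }
    }
  }
  if (anchors.empty()) return;
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& x, const Anchor& y) {
              if (x.ref != y.ref) return x.ref < y.ref;
              if (x.diag != y.diag) return x.diag < y.diag;
              return x.q < y.q;
            });
  size_t start = 0;
  for (size_t i = 1; i <= anchors.size(); ++i) {
    bool close = (i == anchors.size()) ||
                 (anchors[i].ref != anchors[start].ref) ||
                 (anchors[i].diag - anchors[i - 1].diag > DIAG_BAND);
    if (close) {
      if ((int)(i - start) >= min_anchors) {
        std::vector<Anchor> cl(anchors.begin() + start, anchors.begin() + i);
        process_cluster(q, refs[cl[0].ref], cl[0].ref, strand, cl, k, min_id,
                        min_len, out);
      }
      start = i;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_map(CharacterVector qseqs, CharacterVector rseqs, int k,
             double min_id, int min_len, int max_occ, int min_anchors,
             bool both_strands) {
  std::vector<std::string> refs(rseqs.size());
  for (int i = 0; i < rseqs.size(); ++i) refs[i] = as<std::string>(rseqs[i]);
  Index idx;
  idx.build(refs, k, max_occ);
  // query-side seed sampling preserving the sensitivity contract: an exact
  // stretch of max(min_len, 2k) bases must still yield >= min_anchors seeds
  int w = std::max(min_len, 2 * k);
  int stride = std::max(1, std::min((w - k + 1) / (2 * std::max(1, min_anchors)), 8));

  std::vector<int> o_q, o_r, o_qs, o_qe, o_ss, o_se;
  std::vector<long> o_m, o_c, o_sc;
  std::vector<char> o_st;

  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string q = as<std::string>(qseqs[qi]);
    std::vector<Hit> hits;
    map_one(q, refs, idx, '+', min_id, min_len, min_anchors, stride, hits);
    if (both_strands) {
      std::string qrc = revcomp(q);
      std::vector<Hit> rc_hits;
      map_one(qrc, refs, idx, '-', min_id, min_len, min_anchors, stride, rc_hits);
      int L = (int)q.size();
      for (Hit& h : rc_hits) {
        int nqs = L - h.qend, nqe = L - h.qstart;
        h.qstart = nqs; h.qend = nqe;
        hits.push_back(h);
      }
    }
    for (const Hit& h : hits) {
      o_q.push_back(qi + 1); o_r.push_back(h.ref + 1);
      o_qs.push_back(h.qstart); o_qe.push_back(h.qend);
      o_ss.push_back(h.sstart); o_se.push_back(h.send);
      o_st.push_back(h.strand);
      o_m.push_back(h.matches); o_c.push_back(h.cols); o_sc.push_back(h.score);
    }
  }
  int n = (int)o_q.size();
  IntegerVector qv(n), rv(n), qsv(n), qev(n), ssv(n), sev(n);
  NumericVector mv(n), cv(n), scv(n);
  CharacterVector stv(n);
  for (int i = 0; i < n; ++i) {
    qv[i] = o_q[i]; rv[i] = o_r[i];
    qsv[i] = o_qs[i]; qev[i] = o_qe[i]; ssv[i] = o_ss[i]; sev[i] = o_se[i];
    mv[i] = (double)o_m[i]; cv[i] = (double)o_c[i]; scv[i] = (double)o_sc[i];
    stv[i] = std::string(1, o_st[i]);
  }
  return List::create(_["query"] = qv, _["subject"] = rv, _["qstart"] = qsv,
                      _["qend"] = qev, _["sstart"] = ssv, _["send"] = sev,
                      _["strand"] = stv, _["matches"] = mv,
                      _["aln_len"] = cv, _["score"] = scv);
}

// ------------------------------------------------------------- proteins

namespace {

const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";

// BLOSUM62
const int B62[24][24] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

int aacode(char c) {
  const char* p = strchr(AA_ORDER, toupper(c));
  if (p == nullptr) return 22;  // X
  return (int)(p - AA_ORDER);
}

const int AA_GAP_OPEN = 11, AA_GAP_EXT = 1;

// best local alignment score + identity (Smith-Waterman, affine gaps)
void sw_protein(const std::string& A, const std::string& B, long& best_score,
                long& matches, long& cols) {
  int na = (int)A.size(), nb = (int)B.size();
  best_score = 0; matches = 0; cols = 0;
  if (na == 0 || nb == 0) return;
  std::vector<int> ca(na), cb(nb);
  for (int i = 0; i < na; ++i) ca[i] = aacode(A[i]);
  for (int j = 0; j < nb; ++j) cb[j] = aacode(B[j]);
  int W = nb + 1;
  std::vector<long> M((na + 1) * W, 0), X((na + 1) * W, NEG_INF),
      Y((na + 1) * W, NEG_INF);
  // traceback: which matrix fed each cell ('M','X','Y'; 0 = local start/stop)
  std::vector<char> tbM((size_t)(na + 1) * W, 0),
      tbX((size_t)(na + 1) * W, 0), tbY((size_t)(na + 1) * W, 0);
  long best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      long xo = M[(i - 1) * W + j] - AA_GAP_OPEN - AA_GAP_EXT;
      long xe = X[(i - 1) * W + j] - AA_GAP_EXT;
      if (xo >= xe) { X[i * W + j] = xo; tbX[(size_t)i * W + j] = 'M'; }
      else { X[i * W + j] = xe; tbX[(size_t)i * W + j] = 'X'; }
      long yo = M[i * W + j - 1] - AA_GAP_OPEN - AA_GAP_EXT;
      long ye = Y[i * W + j - 1] - AA_GAP_EXT;
      if (yo >= ye) { Y[i * W + j] = yo; tbY[(size_t)i * W + j] = 'M'; }
      else { Y[i * W + j] = ye; tbY[(size_t)i * W + j] = 'Y'; }
      long d = M[(i - 1) * W + j - 1]; char dtb = 'M';
      if (X[(i - 1) * W + j - 1] > d) { d = X[(i - 1) * W + j - 1]; dtb = 'X'; }
      if (Y[(i - 1) * W + j - 1] > d) { d = Y[(i - 1) * W + j - 1]; dtb = 'Y'; }
      long m = d + B62[ca[i - 1]][cb[j - 1]];
      if (m < 0) { m = 0; dtb = 0; }
      M[i * W + j] = m;
      tbM[(size_t)i * W + j] = dtb;
      if (m > best) { best = m; bi = i; bj = j; }
    }
  }
  best_score = best;
  if (best <= 0) return;
  int i = bi, j = bj;
  char state = 'M';
  while (i > 0 && j > 0) {
    if (state == 'M') {
      char prev = tbM[(size_t)i * W + j];
      cols += 1;
      if (ca[i - 1] == cb[j - 1]) matches += 1;
      --i; --j;
      if (prev == 0) break;
      state = prev;
    } else if (state == 'X') {
      char prev = tbX[(size_t)i * W + j];
      cols += 1; --i;
      state = prev;
    } else {
      char prev = tbY[(size_t)i * W + j];
      cols += 1; --j;
      state = prev;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_protein_matrix(CharacterVector a, CharacterVector b) {
  int na = a.size(), nb = b.size();
  NumericMatrix score(na, nb), pident(na, nb), ncols(na, nb);
  for (int i = 0; i < na; ++i) {
    std::string A = as<std::string>(a[i]);
    for (int j = 0; j < nb; ++j) {
      std::string B = as<std::string>(b[j]);
      long s, m, c;
      sw_protein(A, B, s, m, c);
      score(i, j) = (double)s;
      pident(i, j) = (c > 0) ? 100.0 * (double)m / (double)c : 0.0;
      ncols(i, j) = (double)c;
    }
  }
  return List::create(_["score"] = score, _["pident"] = pident,
                      _["aln_len"] = ncols);
}

// ------------------------------------------------------- k-mer utilities

// per-read median multiplicity of its canonical k-mers across the whole set
// [[Rcpp::export]]
NumericVector cpp_kmer_depth(CharacterVector reads, int k) {
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, uint32_t> counts;
  std::vector<std::string> rs(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    rs[r] = as<std::string>(reads[r]);
    const std::string& s = rs[r];
    uint64_t val = 0, rcv = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = basecode(s[i]);
      if (c < 0) { run = 0; val = 0; rcv = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (++run >= k) counts[std::min(val, rcv)]++;
    }
  }
  NumericVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    const std::string& s = rs[r];
    std::vector<uint32_t> mult;
    uint64_t val = 0, rcv = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = basecode(s[i]);
      if (c < 0) { run = 0; val = 0; rcv = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (++run >= k) mult.push_back(counts[std::min(val, rcv)]);
    }
    if (mult.empty()) { out[r] = NA_REAL; continue; }
    std::nth_element(mult.begin(), mult.begin() + mult.size() / 2, mult.end());
    out[r] = (double)mult[mult.size() / 2];
  }
  return out;
}

// ------------------------------------------- order-3 Markov chain sampler

// trans: 64 x 4 row-stochastic matrix, rows indexed by the previous 3-mer
// (2-bit encoded, A=0 C=1 G=2 T=3). Uses R's RNG.
// [[Rcpp::export]]
std::string cpp_markov_gen(int L, NumericMatrix trans) {
  const char BASES[] = "ACGT";
  std::string out;
  out.reserve(L);
  int state = 0;
  // seed the first three bases uniformly
  for (int i = 0; i < 3 && i < L; ++i) {
    int b = (int)std::floor(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out.push_back(BASES[b]);
    state = ((state << 2) | b) & 63;
  }
  for (int i = 3; i < L; ++i) {
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(state, j);
      if (u <= acc) { b = j; break; }
    }
    out.push_back(BASES[b]);
    state = ((state << 2) | b) & 63;
  }
  return out;
}
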
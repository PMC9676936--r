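#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Edit-operation codes shared with the R side:
// 1 = M (match), 2 = X (mismatch), 3 = I (insertion in read),
// 4 = D (deletion from reference), 5 = S (soft clip, read only)
static const int OP_M = 1, OP_X = 2, OP_I = 3, OP_D = 4, OP_S = 5;

struct OpRun {
  std::vector<int> op;
  std::vector<int> len;
  void push(int o, int l) {
    if (l <= 0) return;
    if (!op.empty() && op.back() == o) { len.back() += l; return; }
    op.push_back(o); len.push_back(l);
  }
  void append(const OpRun& other) {
    for (size_t i = 0; i < other.op.size(); ++i) push(other.op[i], other.len[i]);
  }
};

// Affine-gap global DP over a[ia,ib) x b[ja,jb), both ends anchored.
// Gap cost = gapO + gapE * len. Ops appended to out (I = gap in b/ref side
// consuming a; D = gap in a side consuming b).
static void nwSegment(const char* a, int ia, int ib,
                      const char* b, int ja, int jb,
                      double match, double mismatch, double gapO, double gapE,
                      OpRun& out) {
  const int n = ib - ia, m = jb - ja;
  if (n == 0 && m == 0) return;
  if (n == 0) { out.push(OP_D, m); return; }
  if (m == 0) { out.push(OP_I, n); return; }
  const double NEG = -1e18;
  // three-state affine DP with traceback
  std::vector<double> Hp(m + 1), Ep(m + 1), Fp(m + 1), H(m + 1), E(m + 1), F(m + 1);
  // traceback: 2 bits per state per cell
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  // tb encodes, per cell: bits 0-1 H-source (0 diag,1 E,2 F), bit 2 E-extend, bit 3 F-extend
  // state E consumes a (vertical, I ops); state F consumes b (horizontal, D ops)
  Hp[0] = 0; Ep[0] = NEG; Fp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Fp[j] = -(gapO + gapE * j);  // top row: gap consuming b => D ops
    Hp[j] = Fp[j]; Ep[j] = NEG;
    tb[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    H[0] = -(gapO + gapE * i); E[0] = H[0]; F[0] = NEG;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      unsigned char t = 0;
      double e_open = Hp[j] != NEG ? Hp[j] - gapO - gapE : NEG;
      double e_ext = Ep[j] != NEG ? Ep[j] - gapE : NEG;
      double fv, ev;
      // NOTE: E here extends in i (gap in b => I ops), F extends in j (gap in a => D ops)
      if (e_ext > e_open) { ev = e_ext; t |= 4; } else ev = e_open;
      double f_open = H[j - 1] != NEG ? H[j - 1] - gapO - gapE : NEG;
      double f_ext = F[j - 1] != NEG ? F[j - 1] - gapE : NEG;
      if (f_ext > f_open) { fv = f_ext; t |= 8; } else fv = f_open;
      double diag = Hp[j - 1] + (a[ia + i - 1] == b[ja + j - 1] ? match : -mismatch);
      double hv = diag; int src = 0;
      if (ev > hv) { hv = ev; src = 1; }
      if (fv > hv) { hv = fv; src = 2; }
      t |= src;
      E[j] = ev; F[j] = fv; H[j] = hv;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(Hp, H); std::swap(Ep, E); std::swap(Fp, F);
  }
  // traceback from (n, m)
  OpRun rev;
  int i = n, j = m, state = 0;  // 0 = H, 1 = E(I), 2 = F(D)
  while (i > 0 || j > 0) {
    if (state == 0 && i == 0) { rev.push(OP_D, j); break; }
    if (state == 0 && j == 0) { rev.push(OP_I, i); break; }
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) state = t & 3;
    if (state == 0) {
      rev.push(a[ia + i - 1] == b[ja + j - 1] ? OP_M : OP_X, 1);
      --i; --j;
    } else if (state == 1) {
      rev.push(OP_I, 1);
      state = (t & 4) ? 1 : 0; --i;
    } else {
      rev.push(OP_D, 1);
      state = (t & 8) ? 2 : 0; --j;
    }
  }
  // reverse into out
  for (int k = (int)rev.op.size() - 1; k >= 0; --k) out.push(rev.op[k], rev.len[k]);
}

// [[Rcpp::export]]
List cpp_nw_ops(std::string a, std::string b, double match, double mismatch,
                double gapO, double gapE) {
  double cells = (double)(a.size() + 1) * (b.size() + 1);
  if (cells > 6.5e7)
    stop("sequences too long for full dynamic programming");
  OpRun out;
  nwSegment(a.c_str(), 0, (int)a.size(), b.c_str(), 0, (int)b.size(),
            match, mismatch, gapO, gapE, out);
  return List::create(_["op"] = wrap(out.op), _["len"] = wrap(out.len));
}

// Chain colinear anchors maximising anchored bases minus gap penalties.
// Anchors are maximal exact diagonal runs (qstart, rstart, len), 0-based.
// Returns 1-based indices of the chained anchors in query order.
// [[Rcpp::export]]
IntegerVector cpp_chain(IntegerVector qstart, IntegerVector rstart,
                        IntegerVector len, double gapCoef, double joinCost) {
  const int n = qstart.size();
  if (n == 0) return IntegerVector(0);
  // sort by qstart then rstart
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (qstart[x] != qstart[y]) return qstart[x] < qstart[y];
    return rstart[x] < rstart[y];
  });
  std::vector<double> score(n);
  std::vector<int> prev(n, -1);
  double best = -1e18; int bestI = 0;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    score[ii] = len[i];
    for (int jj = ii - 1; jj >= 0; --jj) {
      int j = ord[jj];
      int qgap = qstart[i] - (qstart[j] + len[j]);
      int rgap = rstart[i] - (rstart[j] + len[j]);
      // chance co-diagonal extension can make anchors overlap slightly;
      // permit the join with the successor's head trimmed
      int ov = std::max(0, std::max(-qgap, -rgap));
      if (ov >= len[i]) continue;
      qgap += ov; rgap += ov;
      if (qgap < 0 || rgap < 0) continue;
      double pen = joinCost + gapCoef * std::abs(qgap - rgap)
                 + 0.01 * std::min(qgap, rgap);
      double s = score[jj] + (len[i] - ov) - pen;
      if (s > score[ii]) { score[ii] = s; prev[ii] = jj; }
    }
    if (score[ii] > best) { best = score[ii]; bestI = ii; }
  }
  std::vector<int> chain;
  for (int k = bestI; k >= 0; k = prev[k]) chain.push_back(ord[k] + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// Head/tail handler: free-start corner alignment. Aligns a[0,qh) vs b window
// ending flush; leading unaligned read bases become soft clips.
static int headAlign(const char* q, int qh, const char* r, int rAvail, int rEnd,
                     double match, double mismatch, double gapO, double gapE,
                     OpRun& out) {
  // returns ref start consumed (number of ref bases covered before rEnd)
  if (qh == 0) return 0;
  int w = std::min(rAvail, qh + 30);
  if (w == 0) { out.push(OP_S, qh); return 0; }
  const int n = qh, m = w;
  std::vector<double> Hp(m + 1), H(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  // simple linear-gap DP with free start on both (H(i,0)=0 treated as soft-clip entry,
  // H(0,j)=0 as unaligned ref); must end at (n, m)
  for (int j = 0; j <= m; ++j) Hp[j] = 0;
  const char* rw = r + (rEnd - w);
  for (int i = 1; i <= n; ++i) {
    H[0] = 0; tb[(size_t)i * (m + 1)] = 3;  // enter via soft clip
    for (int j = 1; j <= m; ++j) {
      double diag = Hp[j - 1] + (q[i - 1] == rw[j - 1] ? match : -mismatch);
      double up = Hp[j] - (gapO + gapE);     // I
      double left = H[j - 1] - (gapO + gapE); // D
      double hv = diag; unsigned char t = 0;
      if (up > hv) { hv = up; t = 1; }
      if (left > hv) { hv = left; t = 2; }
      // free restart only from column 0 handled by H[0]=0 entry
      H[j] = hv; tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(Hp, H);
  }
  OpRun rev;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) { rev.push(q[i - 1] == rw[j - 1] ? OP_M : OP_X, 1); --i; --j; }
    else if (t == 1) { rev.push(OP_I, 1); --i; }
    else if (t == 2) { rev.push(OP_D, 1); --j; }
    else break;
  }
  if (i > 0) rev.push(OP_S, i);
  int refConsumed = m - j;
  for (int k = (int)rev.op.size() - 1; k >= 0; --k) out.push(rev.op[k], rev.len[k]);
  return refConsumed;
}

// Refine a chained anchor skeleton into full run-length edit operations.
// qseq/rseq are read and reference; anchors 0-based (already chained, colinear).
// maxDPcells bounds inter-anchor DP; larger gaps fall back to a direct
// match-run + single-indel representation (keeps multi-kb SVs as one op).
// [[Rcpp::export]]
List cpp_refine(std::string qseq, std::string rseq,
                IntegerVector aq, IntegerVector ar, IntegerVector alen,
                double match, double mismatch, double gapO, double gapE,
                double maxDPcells) {
  const char* q = qseq.c_str();
  const char* r = rseq.c_str();
  const int nq = (int)qseq.size();
  const int nA = aq.size();
  if (nA == 0) stop("no anchors to refine");
  OpRun out;
  // head
  int headRef = headAlign(q, aq[0], r, ar[0], ar[0], match, mismatch, gapO, gapE, out);
  int refStart = ar[0] - headRef;
  // anchors + gaps
  for (int k = 0; k < nA; ++k) {
    if (k > 0) {
      int qa = aq[k - 1] + alen[k - 1], qb = aq[k];
      int ra = ar[k - 1] + alen[k - 1], rb = ar[k];
      int ql = qb - qa, rl = rb - ra;
      if (ql < 0 || rl < 0) stop("anchors not colinear");
      if ((double)(ql + 1) * (rl + 1) <= maxDPcells || ql == 0 || rl == 0) {
        nwSegment(q, qa, qb, r, ra, rb, match, mismatch, gapO, gapE, out);
      } else {
        int mm = std::min(ql, rl);
        for (int t = 0; t < mm; ++t)
          out.push(q[qa + t] == r[ra + t] ? OP_M : OP_X, 1);
        if (ql > rl) out.push(OP_I, ql - rl); else out.push(OP_D, rl - ql);
      }
    }
    out.push(OP_M, alen[k]);
  }
  // tail
  {
    int qa = aq[nA - 1] + alen[nA - 1];
    int ra = ar[nA - 1] + alen[nA - 1];
    int qh = nq - qa;
    int rAvail = (int)rseq.size() - ra;
    if (qh > 0) {
      int w = std::min(rAvail, qh + 30);
      // mirror of headAlign: reverse both and reuse
      std::string qr(qseq.rbegin(), qseq.rend());
      std::string rr(rseq.rbegin(), rseq.rend());
      OpRun tail;
      int tailRef = headAlign(qr.c_str() + (nq - qa - qh), qh,
                              rr.c_str() + ((int)rseq.size() - ra - w), w, w,
                              match, mismatch, gapO, gapE, tail);
      (void)tailRef;
      // tail ops are in reversed orientation; flip run order
      OpRun flip;
      for (int k2 = (int)tail.op.size() - 1; k2 >= 0; --k2)
        flip.push(tail.op[k2], tail.len[k2]);
      out.append(flip);
    }
  }
  // stats
  long mM = 0, mX = 0, mI = 0, mD = 0, mS = 0;
  double score = 0; bool inI = false, inD = false;
  for (size_t k = 0; k < out.op.size(); ++k) {
    int o = out.op[k], l = out.len[k];
    if (o == OP_M) { mM += l; score += match * l; inI = inD = false; }
    else if (o == OP_X) { mX += l; score -= mismatch * l; inI = inD = false; }
    else if (o == OP_I) { mI += l; score -= gapO + gapE * l; inD = false; }
    else if (o == OP_D) { mD += l; score -= gapO + gapE * l; inI = false; }
    else mS += l;
  }
  int refEnd = refStart;
  for (size_t k = 0; k < out.op.size(); ++k) {
    int o = out.op[k];
    if (o == OP_M || o == OP_X || o == OP_D) refEnd += out.len[k];
  }
  return List::create(
    _["op"] = wrap(out.op), _["len"] = wrap(out.len),
    _["ref_start"] = refStart, _["ref_end"] = refEnd,
    _["matches"] = (double)mM, _["mismatches"] = (double)mX,
    _["ins"] = (double)mI, _["del"] = (double)mD, _["clip"] = (double)mS,
    _["score"] = score);
}

// Scan a read for approximate occurrences of a barcode (edit distance <=
// maxEdits) using pigeonhole seeding: the barcode is split into maxEdits+1
// pieces; any hit must contain one piece exactly.
// Returns a matrix with columns (start, edits), 1-based starts, deduplicated
// to local best hits.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_barcode(std::string read, std::string barcode, int maxEdits) {
  const int n = (int)read.size(), b = (int)barcode.size();
  std::vector<std::pair<int,int>> hits;  // (start0, edits)
  if (n >= b - maxEdits && b > 0) {
    int pieces = maxEdits + 1;
    std::vector<int> cand;
    for (int p = 0; p < pieces; ++p) {
      int ps = (int)((long)b * p / pieces);
      int pe = (int)((long)b * (p + 1) / pieces);
      int pl = pe - ps;
      if (pl <= 0) continue;
      const char* pat = barcode.c_str() + ps;
      for (int i = 0; i + pl <= n; ++i) {
        if (std::memcmp(read.c_str() + i, pat, pl) == 0)
          cand.push_back(i - ps);  // implied barcode start
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    // verify candidates with banded semi-global DP (barcode fully aligned)
    int lastStart = -1000000, lastEdits = maxEdits + 1;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int s0 = cand[ci];
      int ws = std::max(0, s0 - maxEdits);
      int we = std::min(n, s0 + b + maxEdits);
      int m = we - ws;
      if (m < b - maxEdits) continue;
      // DP rows barcode, cols window; free start/end in window
      std::vector<int> prev(m + 1), cur(m + 1);
      for (int j = 0; j <= m; ++j) prev[j] = 0;
      for (int i = 1; i <= b; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
          int c = prev[j - 1] + (barcode[i - 1] == read[ws + j - 1] ? 0 : 1);
          c = std::min(c, prev[j] + 1);
          c = std::min(c, cur[j - 1] + 1);
          cur[j] = c;
        }
        std::swap(prev, cur);
      }
      int bestE = maxEdits + 1, bestJ = -1;
      for (int j = 0; j <= m; ++j)
        if (prev[j] < bestE) { bestE = prev[j]; bestJ = j; }
      if (bestE > maxEdits) continue;
      int start0 = ws + std::max(0, bestJ - b);
      // merge with previous hit if overlapping
      if (!hits.empty() && start0 - hits.back().first < b) {
        if (bestE < hits.back().second) hits.back() = std::make_pair(start0, bestE);
      } else {
        hits.push_back(std::make_pair(start0, bestE));
      }
      (void)lastStart; (void)lastEdits;
    }
  }
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first + 1;
    out(i, 1) = hits[i].second;
  }
  colnames(out) = CharacterVector::create("start", "edits");
  return out;
}
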
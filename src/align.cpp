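#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh three-state affine-gap alignment with optional banding and optional
// free end gaps in the reference (used for amplicon reads that may not span
// the reference ends). Gap of length L costs gap_open + L * gap_extend,
// the convention Biostrings::pairwiseAlignment uses.
//
// States: M (diagonal), X (insertion: consumes query, gap in reference),
// Y (deletion: consumes reference, gap in query). X<->Y transitions are
// allowed and each opens a new gap, so the optimum ranges over all op
// strings with independently charged gap runs.
//
// Traceback tie-break: M > Y (deletion) > X (insertion), giving
// deterministic CIGARs.

static const double NEG_INF = -1e18;

// packed traceback byte: bits 0-1 predecessor of M (0=M,1=X,2=Y,3=origin),
// bits 2-3 predecessor of X, bits 4-5 predecessor of Y.
static inline int tb_m(unsigned char b) { return b & 3; }
static inline int tb_x(unsigned char b) { return (b >> 2) & 3; }
static inline int tb_y(unsigned char b) { return (b >> 4) & 3; }

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(std::string query, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int band, bool free_ref_ends) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band <= 0) band = n + m;  // unbanded

  // diagonal offset window: j - i in [dlo, dhi]
  const int dlo = std::min(0, m - n) - band;
  const int dhi = std::max(0, m - n) + band;

  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);  // previous row
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);  // current row
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0u);

  // row 0
  std::fill(Mp.begin(), Mp.end(), NEG_INF);
  std::fill(Xp.begin(), Xp.end(), NEG_INF);
  std::fill(Yp.begin(), Yp.end(), NEG_INF);
  Mp[0] = 0.0;
  tb[0] = 3;  // origin
  for (int j = 1; j <= m; ++j) {
    if (free_ref_ends) {
      Mp[j] = 0.0;               // alignment may start at any reference pos
      tb[j] = 3;
    } else {
      Yp[j] = gap_open + gap_extend * j;
      tb[j] = (unsigned char)((j == 1 ? 0 : 2) << 4);
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Xc.begin(), Xc.end(), NEG_INF);
    std::fill(Yc.begin(), Yc.end(), NEG_INF);
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    // column 0: only X (gap in reference) reaches here
    if (0 - i >= dlo) {
      Xc[0] = gap_open + gap_extend * i;
      tbrow[0] = (unsigned char)((i == 1 ? 0 : 1) << 2);
    }
    const int jlo = std::max(1, i + dlo);
    const int jhi = std::min(m, i + dhi);
    const char qc = query[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char b = 0;
      // M state
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      double best = dM; int who = 0;
      if (dY > best) { best = dY; who = 2; }
      if (dX > best) { best = dX; who = 1; }
      double s = (qc == ref[j - 1]) ? match : mismatch;
      double Mv = (best <= NEG_INF / 2) ? NEG_INF : best + s;
      b |= (unsigned char) who;
      // X state (consumes query i): from row above, same column
      double xo = Mp[j] + gap_open + gap_extend;
      double xx = Xp[j] + gap_extend;
      double xy = Yp[j] + gap_open + gap_extend;
      double Xv = xo; int wx = 0;
      if (xy > Xv) { Xv = xy; wx = 2; }
      if (xx > Xv) { Xv = xx; wx = 1; }
      if (Xv < NEG_INF / 2) Xv = NEG_INF;
      b |= (unsigned char)(wx << 2);
      // Y state (consumes ref j): from same row, previous column
      double yo = Mc[j - 1] + gap_open + gap_extend;
      double yx = Xc[j - 1] + gap_open + gap_extend;
      double yy = Yc[j - 1] + gap_extend;
      double Yv = yo; int wy = 0;
      if (yy > Yv) { Yv = yy; wy = 2; }
      if (yx > Yv) { Yv = yx; wy = 1; }
      if (Yv < NEG_INF / 2) Yv = NEG_INF;
      b |= (unsigned char)(wy << 4);
      Mc[j] = Mv; Xc[j] = Xv; Yc[j] = Yv;
      tbrow[j] = b;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  // terminal cell/state
  int end_j = m, state = 0;
  double score;
  if (free_ref_ends) {
    score = NEG_INF;
    for (int j = 0; j <= m; ++j) {
      // trailing reference bases are free: alignment may end in M or X
      if (Mp[j] > score) { score = Mp[j]; end_j = j; state = 0; }
      if (Xp[j] > score) { score = Xp[j]; end_j = j; state = 1; }
    }
  } else {
    score = Mp[m]; state = 0;
    if (Yp[m] > score) { score = Yp[m]; state = 2; }
    if (Xp[m] > score) { score = Xp[m]; state = 1; }
  }
  if (score < NEG_INF / 2)
    stop("band too narrow: no alignment found within the band");

  // traceback
  std::string ops;  // reversed op chars
  ops.reserve(n + m);
  int i = n, j = end_j;
  while (true) {
    unsigned char b = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      int pre = tb_m(b);
      if (pre == 3) break;  // origin (i==0; j is ref_start)
      ops.push_back('M');
      --i; --j; state = pre;
    } else if (state == 1) {
      ops.push_back('I');
      int pre = tb_x(b);
      --i; state = (pre == 0) ? 0 : (pre == 1 ? 1 : 2);
    } else {
      ops.push_back('D');
      int pre = tb_y(b);
      --j; state = (pre == 0) ? 0 : (pre == 1 ? 1 : 2);
    }
    if (i == 0 && j == 0) break;
  }
  int ref_start = j;
  std::reverse(ops.begin(), ops.end());

  // run-length encode into CIGAR vectors
  std::vector<int> lens;
  std::string opchars;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (!opchars.empty() && opchars.back() == ops[k]) {
      lens.back() += 1;
    } else {
      opchars.push_back(ops[k]);
      lens.push_back(1);
    }
  }
  CharacterVector op_out(opchars.size());
  IntegerVector len_out(lens.size());
  for (size_t k = 0; k < lens.size(); ++k) {
    op_out[k] = std::string(1, opchars[k]);
    len_out[k] = lens[k];
  }

  return List::create(
    _["score"] = score,
    _["op"] = op_out,
    _["len"] = len_out,
    _["ref_start"] = ref_start,
    _["ref_end"] = end_j);
}

// Score-only banded alignment used by the read classifier (no traceback).
// [[Rcpp::export(name = ".affine_score_cpp")]]
double affine_score_cpp(std::string query, std::string ref,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        int band, bool free_ref_ends) {
  List res = affine_align_cpp(query, ref, match, mismatch, gap_open,
                              gap_extend, band, free_ref_ends);
  return as<double>(res["score"]);
}
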
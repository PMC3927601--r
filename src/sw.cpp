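#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with traceback.
//
// q, s: sequences encoded as 0-based indices into `smat`; negative codes
// are alignable but score as the matrix's worst entry (unknown residues).
// Gap of length k costs gap_open + k * gap_extend (open charged once, on
// top of the per-residue extension), matching the convention used by the
// reference dynamic-programming implementations this engine is tested
// against.
//
// Returns the best-scoring local alignment: raw score, 1-based inclusive
// query/subject bounds, number of aligned columns, matches, and gap count.
// Score 0 means no positive-scoring local alignment exists.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix smat,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  int worst = smat(0, 0);
  for (int i = 0; i < smat.nrow(); ++i)
    for (int j = 0; j < smat.ncol(); ++j)
      if (smat(i, j) < worst) worst = smat(i, j);

  std::vector<int> Hprev(m + 1, 0), H(m + 1, 0), E(m + 1, NEG);
  // trace: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  // plus bits for E/F continuation
  std::vector<unsigned char> trace((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> etrace((size_t)(n + 1) * (m + 1), 0); // 1: E came from E
  std::vector<unsigned char> ftrace((size_t)(n + 1) * (m + 1), 0); // 1: F came from F

  int best = 0, bi = 0, bj = 0;
  std::vector<int> Fcol(m + 1, NEG);

  for (int i = 1; i <= n; ++i) {
    int qc = q[i - 1];
    H[0] = 0;
    int Erow = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in query (consume subject), horizontal
      int e_open = H[j - 1] - gap_open - gap_extend;
      int e_ext  = Erow - gap_extend;
      Erow = (e_open >= e_ext) ? e_open : e_ext;
      etrace[idx] = (e_open >= e_ext) ? 0 : 1;
      // F: gap in subject (consume query), vertical
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext  = Fcol[j] - gap_extend;
      Fcol[j] = (f_open >= f_ext) ? f_open : f_ext;
      ftrace[idx] = (f_open >= f_ext) ? 0 : 1;

      int sc = s[j - 1];
      int sub = (qc >= 0 && sc >= 0) ? smat(qc, sc) : worst;
      int diag = Hprev[j - 1] + sub;
      int h = 0; unsigned char tr = 0;
      if (diag > h) { h = diag; tr = 1; }
      if (Fcol[j] > h) { h = Fcol[j]; tr = 2; }
      if (Erow > h) { h = Erow; tr = 3; }
      H[j] = h; trace[idx] = tr;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, H);
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aligned_length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0);

  // traceback
  int i = bi, j = bj, matches = 0, cols = 0, gaps = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char tr = trace[idx];
      if (tr == 0) break;
      if (tr == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1] && q[i - 1] >= 0) ++matches;
        --i; --j;
      } else if (tr == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, move left
      ++cols; ++gaps;
      unsigned char et = etrace[idx];
      --j;
      if (et == 0) state = 0;
    } else { // F: gap in subject, move up
      ++cols; ++gaps;
      unsigned char ft = ftrace[idx];
      --i;
      if (ft == 0) state = 0;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1,
                      _["s_end"] = bj, _["aligned_length"] = cols,
                      _["matches"] = matches, _["gaps"] = gaps);
}

// Score-only variant without traceback storage (O(m) memory), for
// property checks on many pairs.
// [[Rcpp::export]]
int sw_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix smat,
                 int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  int worst = smat(0, 0);
  for (int i = 0; i < smat.nrow(); ++i)
    for (int j = 0; j < smat.ncol(); ++j)
      if (smat(i, j) < worst) worst = smat(i, j);
  std::vector<int> Hprev(m + 1, 0), H(m + 1, 0), Fcol(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int qc = q[i - 1];
    H[0] = 0;
    int Erow = NEG;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[j - 1] - gap_open - gap_extend, Erow - gap_extend);
      Erow = e;
      int f = std::max(Hprev[j] - gap_open - gap_extend, Fcol[j] - gap_extend);
      Fcol[j] = f;
      int sc = s[j - 1];
      int sub = (qc >= 0 && sc >= 0) ? smat(qc, sc) : worst;
      int h = std::max(0, Hprev[j - 1] + sub);
      h = std::max(h, std::max(e, f));
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, H);
  }
  return best;
}
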
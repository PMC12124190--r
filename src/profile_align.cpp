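#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two alignment profiles with
// affine gap penalties.  Symbols are integer codes 0..21 where 20 is the X
// intron marker and 21 is a gap; the 22x22 score matrix M carries zeros in
// the X and gap rows/columns.  Column-against-column score is the mean
// pairwise substitution score between the two frequency profiles.  Ties in
// the traceback prefer diagonal, then a gap in profile A, then a gap in
// profile B, which makes the merge deterministic for a fixed input order.
//
// Returns the alignment score and, for each merged column, the source column
// (1-based) consumed from A and from B (0 where a gap was inserted).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix M,
                       double gap_open, double gap_ext) {
  const int nA = A.nrow(), LA = A.ncol();
  const int nB = B.nrow(), LB = B.ncol();
  const int K = M.nrow(); // 22

  // frequency profiles (K x L)
  std::vector<double> PA((size_t)K * LA, 0.0), PB((size_t)K * LB, 0.0);
  for (int j = 0; j < LA; ++j)
    for (int i = 0; i < nA; ++i) PA[(size_t)j * K + A(i, j)] += 1.0 / nA;
  for (int j = 0; j < LB; ++j)
    for (int i = 0; i < nB; ++i) PB[(size_t)j * K + B(i, j)] += 1.0 / nB;

  // T = M * PB, then S(i,j) = PA_i . T_j
  std::vector<double> T((size_t)K * LB, 0.0);
  for (int j = 0; j < LB; ++j) {
    for (int b = 0; b < K; ++b) {
      double fb = PB[(size_t)j * K + b];
      if (fb == 0.0) continue;
      for (int a = 0; a < K; ++a) T[(size_t)j * K + a] += M(a, b) * fb;
    }
  }

  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> H((size_t)(LA + 1) * (LB + 1), NEG);
  std::vector<double> E(H.size(), NEG), F(H.size(), NEG);
  // traceback: for H, 0 = diag, 1 = from E (gap in A), 2 = from F (gap in B)
  std::vector<unsigned char> tbH(H.size(), 0), tbE(H.size(), 0), tbF(H.size(), 0);
  auto at = [LB](int i, int j) { return (size_t)i * (LB + 1) + j; };

  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= LB; ++j) {
    E[at(0, j)] = -(gap_open + j * gap_ext);
    H[at(0, j)] = E[at(0, j)];
    tbH[at(0, j)] = 1;
    tbE[at(0, j)] = 1; // extension
  }
  for (int i = 1; i <= LA; ++i) {
    F[at(i, 0)] = -(gap_open + i * gap_ext);
    H[at(i, 0)] = F[at(i, 0)];
    tbH[at(i, 0)] = 2;
    tbF[at(i, 0)] = 1;
  }

  for (int i = 1; i <= LA; ++i) {
    const double *pa = &PA[(size_t)(i - 1) * K];
    for (int j = 1; j <= LB; ++j) {
      // substitution score of column i of A vs column j of B
      const double *tj = &T[(size_t)(j - 1) * K];
      double s = 0.0;
      for (int a = 0; a < K; ++a) s += pa[a] * tj[a];

      double e_open = H[at(i, j - 1)] - (gap_open + gap_ext);
      double e_ext = E[at(i, j - 1)] - gap_ext;
      if (e_open >= e_ext) { E[at(i, j)] = e_open; tbE[at(i, j)] = 0; }
      else { E[at(i, j)] = e_ext; tbE[at(i, j)] = 1; }

      double f_open = H[at(i - 1, j)] - (gap_open + gap_ext);
      double f_ext = F[at(i - 1, j)] - gap_ext;
      if (f_open >= f_ext) { F[at(i, j)] = f_open; tbF[at(i, j)] = 0; }
      else { F[at(i, j)] = f_ext; tbF[at(i, j)] = 1; }

      double d = H[at(i - 1, j - 1)] + s;
      double best = d; unsigned char tb = 0;
      if (E[at(i, j)] > best) { best = E[at(i, j)]; tb = 1; }
      if (F[at(i, j)] > best) { best = F[at(i, j)]; tb = 2; }
      H[at(i, j)] = best; tbH[at(i, j)] = tb;
    }
  }

  // traceback
  std::vector<int> ai, bi;
  int i = LA, j = LB;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  state = tbH[at(i, j)] == 0 ? 0 : tbH[at(i, j)];
  while (i > 0 || j > 0) {
    unsigned char tb = tbH[at(i, j)];
    if (tb == 0 && i > 0 && j > 0) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (tb == 1) { // gap in A: consume B columns until gap closes
      unsigned char ext = 1;
      while (j > 0 && ext == 1) {
        ext = tbE[at(i, j)];
        ai.push_back(0); bi.push_back(j); --j;
        if (ext == 0) break;
      }
    } else { // gap in B
      unsigned char ext = 1;
      while (i > 0 && ext == 1) {
        ext = tbF[at(i, j)];
        ai.push_back(i); bi.push_back(0); --i;
        if (ext == 0) break;
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  (void)state;

  return List::create(_["score"] = H[at(LA, LB)],
                      _["a_cols"] = wrap(ai), _["b_cols"] = wrap(bi));
}
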
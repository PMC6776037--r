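#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Score-only Smith-Waterman with affine gaps (rolling rows); used to pick
// the best frame and gate on E-value before the traceback alignment runs.
// [[Rcpp::export]]
double sw_score_cpp(std::string q, std::string s, NumericMatrix sub,
                    std::string alphabet, double gap_open, double gap_ext) {
  const int nq = static_cast<int>(q.size());
  const int ns = static_cast<int>(s.size());
  std::vector<int> code(256, -1);
  for (int i = 0; i < static_cast<int>(alphabet.size()); ++i) {
    code[static_cast<unsigned char>(alphabet[i])] = i;
  }
  const double NEG = -1e30;
  std::vector<double> Mprev(ns + 1, 0.0), Mcur(ns + 1, 0.0);
  std::vector<double> Xprev(ns + 1, NEG), Xcur(ns + 1, NEG);
  std::vector<double> Yprev(ns + 1, NEG), Ycur(ns + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= nq; ++i) {
    const int ci = code[static_cast<unsigned char>(q[i - 1])];
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    for (int j = 1; j <= ns; ++j) {
      const int cj = code[static_cast<unsigned char>(s[j - 1])];
      const double sc = (ci >= 0 && cj >= 0) ? sub(ci, cj) : -4.0;
      const double x = std::max(Mprev[j] - gap_open - gap_ext, Xprev[j] - gap_ext);
      const double y = std::max(Mcur[j - 1] - gap_open - gap_ext, Ycur[j - 1] - gap_ext);
      double pre = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      double m = pre + sc;
      if (m < 0.0) m = 0.0;
      Mcur[j] = m; Xcur[j] = x; Ycur[j] = y;
      if (m > best) best = m;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

// Plain affine-gap Smith-Waterman local alignment for amino-acid strings.
// Gap of length L costs gap_open + L * gap_ext (NCBI convention). Returns the
// best local score, the aligned span on each sequence, and identity counted
// over all alignment columns including gaps.
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, NumericMatrix sub,
                  std::string alphabet, double gap_open, double gap_ext) {
  const int nq = static_cast<int>(q.size());
  const int ns = static_cast<int>(s.size());
  std::vector<int> code(256, -1);
  for (int i = 0; i < static_cast<int>(alphabet.size()); ++i) {
    code[static_cast<unsigned char>(alphabet[i])] = i;
  }
  const double NEG = -1e30;
  const int W = ns + 1;
  // score matrices: M (match/mismatch), X (gap in s, consumes q), Y (gap in q)
  std::vector<double> M((nq + 1) * W, 0.0), X((nq + 1) * W, NEG),
      Y((nq + 1) * W, NEG);
  // traceback: 0 none, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> tbM((nq + 1) * W, 0), tbX((nq + 1) * W, 0),
      tbY((nq + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    const int ci = code[static_cast<unsigned char>(q[i - 1])];
    for (int j = 1; j <= ns; ++j) {
      const int cj = code[static_cast<unsigned char>(s[j - 1])];
      const double sc = (ci >= 0 && cj >= 0) ? sub(ci, cj) : -4.0;
      const int idx = i * W + j, up = (i - 1) * W + j, left = i * W + j - 1,
                diag = (i - 1) * W + j - 1;
      // X: gap in subject (consume query residue i)
      double xo = M[up] - gap_open - gap_ext, xe = X[up] - gap_ext;
      if (xo >= xe) { X[idx] = xo; tbX[idx] = 1; } else { X[idx] = xe; tbX[idx] = 2; }
      // Y: gap in query (consume subject residue j)
      double yo = M[left] - gap_open - gap_ext, ye = Y[left] - gap_ext;
      if (yo >= ye) { Y[idx] = yo; tbY[idx] = 1; } else { Y[idx] = ye; tbY[idx] = 3; }
      // M
      double m0 = M[diag], x0 = X[diag], y0 = Y[diag];
      double pre = m0; unsigned char tb = 1;
      if (x0 > pre) { pre = x0; tb = 2; }
      if (y0 > pre) { pre = y0; tb = 3; }
      double mval = pre + sc;
      if (mval <= 0.0) { M[idx] = 0.0; tbM[idx] = 0; }
      else { M[idx] = mval; tbM[idx] = tb; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  // traceback from the best M cell
  int i = bi, j = bj, state = 1;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  int columns = 0, identical = 0;
  while (i > 0 && j > 0 && best > 0.0) {
    if (state == 1) {
      // consume the residue pair (i, j)
      ++columns;
      if (q[i - 1] == s[j - 1]) ++identical;
      qstart = i; sstart = j;
      const unsigned char tb = tbM[i * W + j];
      --i; --j;
      if (tb == 0) break;  // defensive: positive M always has a predecessor
      state = tb;
      // alignment starts where the predecessor M cell hit the 0 floor
      if (state == 1 && M[i * W + j] <= 0.0) break;
    } else if (state == 2) {
      ++columns;
      qstart = i;
      const unsigned char tb = tbX[i * W + j];
      --i;
      state = tb;
      if (state == 1 && M[i * W + j] <= 0.0) break;
    } else {
      ++columns;
      sstart = j;
      const unsigned char tb = tbY[i * W + j];
      --j;
      state = tb;
      if (state == 1 && M[i * W + j] <= 0.0) break;
    }
  }
  return List::create(
      _["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send, _["columns"] = columns,
      _["identical"] = identical);
}
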
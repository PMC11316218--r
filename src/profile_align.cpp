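#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (a length-k gap costs
// open + k * extend, matching the pairwise aligner's convention; end gaps
// are penalized). Profiles are 20 x L residue-frequency matrices; gap
// characters contribute nothing to a column's frequency vector. Column pair
// score is fa' S fb. Traceback tie-break is fixed: substitution, then gap in
// the second profile, then gap in the first, so results are deterministic.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                       double gap_open, double gap_extend) {
  const int La = fa.ncol(), Lb = fb.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double gi = gap_open + gap_extend;  // cost of opening a length-1 gap
  const double ge = gap_extend;

  // column pair scores: cs[i][j] = fa_i' S fb_j, via T = S fb
  std::vector<double> T((size_t)20 * Lb);
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < 20; ++a) {
      double s = 0.0;
      for (int b = 0; b < 20; ++b) s += S(a, b) * fb(b, j);
      T[(size_t)j * 20 + a] = s;
    }
  std::vector<double> cs((size_t)La * Lb);
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      double s = 0.0;
      const double* tj = &T[(size_t)j * 20];
      for (int a = 0; a < 20; ++a) s += fa(a, i) * tj[a];
      cs[(size_t)i * Lb + j] = s;
    }

  const size_t W = (size_t)Lb + 1;
  std::vector<double> M((La + 1) * W, NEG), X((La + 1) * W, NEG),
      Y((La + 1) * W, NEG);
  // backpointers: state entered from (0=M,1=X,2=Y)
  std::vector<unsigned char> bM((La + 1) * W), bX((La + 1) * W),
      bY((La + 1) * W);
  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[i * W] = -(gap_open + i * ge);
    bX[i * W] = 1;
  }
  bX[W] = 0;
  for (int j = 1; j <= Lb; ++j) {
    Y[j] = -(gap_open + j * ge);
    bY[j] = 2;
  }
  bY[1] = 0;

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: consume one column from each
      double best = M[d];
      unsigned char bp = 0;
      if (X[d] > best) { best = X[d]; bp = 1; }
      if (Y[d] > best) { best = Y[d]; bp = 2; }
      M[c] = best + cs[(size_t)(i - 1) * Lb + (j - 1)];
      bM[c] = bp;
      // X: consume column i of A against a gap
      best = M[up] - gi; bp = 0;
      if (X[up] - ge > best) { best = X[up] - ge; bp = 1; }
      if (Y[up] - gi > best) { best = Y[up] - gi; bp = 2; }
      X[c] = best; bX[c] = bp;
      // Y: consume column j of B against a gap
      best = M[lf] - gi; bp = 0;
      if (X[lf] - gi > best) { best = X[lf] - gi; bp = 1; }
      if (Y[lf] - ge > best) { best = Y[lf] - ge; bp = 2; }
      Y[c] = best; bY[c] = bp;
    }
  }

  size_t end = (size_t)La * W + Lb;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> pa, pb;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = bM[c]; --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = bX[c]; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = bY[c]; --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb),
                      _["score"] = score);
}
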
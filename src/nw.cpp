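// Affine-gap global alignment (Gotoh) used to fill inter-anchor segments.
// Gap cost convention matches Biostrings::pairwiseAlignment: a gap of
// length L costs gapOpen + L * gapExt.
#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_nw(std::string a, std::string b, double match, double mismatch,
            double gapOpen, double gapExt) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) {
    std::string ga(a), gb(b);
    if (n == 0) ga.assign(m, '-');
    if (m == 0) gb.assign(n, '-');
    double sc = (n + m > 0) ? -(gapOpen + (n + m) * gapExt) : 0.0;
    return List::create(_["a"] = ga, _["b"] = gb, _["score"] = sc);
  }
  const double NEG = -1e18;
  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG), X = M, Y = M;
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0), tbX = tbM, tbY = tbM;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[(size_t)i * W] = -(gapOpen + i * gapExt);
    tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[(size_t)j] = -(gapOpen + j * gapExt);
    tbY[(size_t)j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal move from best of three
      double m0 = M[prow + j - 1], x0 = X[prow + j - 1], y0 = Y[prow + j - 1];
      unsigned char t = 0; double best = m0;
      if (x0 > best) { best = x0; t = 1; }
      if (y0 > best) { best = y0; t = 2; }
      M[row + j] = best + s; tbM[row + j] = t;
      // X: consume a[i-1] against a gap
      double xo = M[prow + j] - gapOpen - gapExt;
      double xe = X[prow + j] - gapExt;
      if (xo >= xe) { X[row + j] = xo; tbX[row + j] = 0; }
      else          { X[row + j] = xe; tbX[row + j] = 1; }
      // Y: consume b[j-1] against a gap
      double yo = M[row + j - 1] - gapOpen - gapExt;
      double ye = Y[row + j - 1] - gapExt;
      if (yo >= ye) { Y[row + j] = yo; tbY[row + j] = 0; }
      else          { Y[row + j] = ye; tbY[row + j] = 1; }
    }
  }
  // traceback from best terminal layer
  size_t end = (size_t)n * W + m;
  int layer = 0; double best = M[end];
  if (X[end] > best) { best = X[end]; layer = 1; }
  if (Y[end] > best) { best = Y[end]; layer = 2; }
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t pos = (size_t)i * W + j;
    if (layer == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      layer = tbM[pos]; --i; --j;
    } else if (layer == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      layer = (tbX[pos] == 0) ? 0 : 1; --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      layer = (tbY[pos] == 0) ? 0 : 2;
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
}
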
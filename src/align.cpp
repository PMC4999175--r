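#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh global alignment with affine gap cost open + k*extend.
// Ties resolved preferring diagonal, then gap-in-b (consume a), then
// gap-in-a, making the traceback deterministic.

static const double NEG = -1e30;

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: which of M/X/Y achieved each cell's max, per matrix
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - i * gap_extend;
    tX[i * W] = 1; // from X (extension)
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - j * gap_extend;
    tY[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal move
      double best = M[d];
      unsigned char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      M[c] = best + s;
      tM[c] = from;
      // X: consume a[i-1], gap in b
      double open_x = M[u] - gap_open - gap_extend;
      double ext_x = X[u] - gap_extend;
      double oy_x = Y[u] - gap_open - gap_extend;
      if (open_x >= ext_x && open_x >= oy_x) { X[c] = open_x; tX[c] = 0; }
      else if (ext_x >= oy_x) { X[c] = ext_x; tX[c] = 1; }
      else { X[c] = oy_x; tX[c] = 2; }
      // Y: consume b[j-1], gap in a
      double open_y = M[l] - gap_open - gap_extend;
      double ox_y = X[l] - gap_open - gap_extend;
      double ext_y = Y[l] - gap_extend;
      if (open_y >= ox_y && open_y >= ext_y) { Y[c] = open_y; tY[c] = 0; }
      else if (ox_y >= ext_y) { Y[c] = ox_y; tY[c] = 1; }
      else { Y[c] = ext_y; tY[c] = 2; }
    }
  }
  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = tX[c];
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = tY[c];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
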
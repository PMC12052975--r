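// Global pairwise alignment with affine gaps (Gotoh three-state recursion).
// Scores are maximised; a gap run of length L costs gap_open + L * gap_extend
// (both penalties passed as negative numbers). Traceback tie-breaking prefers
// diagonal, then up (gap in b), then left (gap in a).
#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, NumericMatrix sub,
                      std::string alphabet, double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<int> code(256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    code[static_cast<unsigned char>(alphabet[i])] = static_cast<int>(i);
  std::vector<int> ai(n), bj(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = code[static_cast<unsigned char>(a[i])];
    if (ai[i] < 0) stop("letter '%c' absent from the substitution matrix", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bj[j] = code[static_cast<unsigned char>(b[j])];
    if (bj[j] < 0) stop("letter '%c' absent from the substitution matrix", b[j]);
  }

  // M: a[i] aligned to b[j]; X: a[i] over gap (up); Y: gap over b[j] (left)
  int R = n + 1, C = m + 1;
  std::vector<double> M(R * C, NEG), X(R * C, NEG), Y(R * C, NEG);
  auto at = [C](int i, int j) { return i * C + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bj[j - 1]);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)], dY = Y[at(i - 1, j - 1)];
      M[at(i, j)] = std::max(dM, std::max(dX, dY)) + s;
      double uM = M[at(i - 1, j)], uX = X[at(i - 1, j)], uY = Y[at(i - 1, j)];
      X[at(i, j)] = std::max(uM + gap_open + gap_extend,
                             std::max(uX + gap_extend, uY + gap_open + gap_extend));
      double lM = M[at(i, j - 1)], lX = X[at(i, j - 1)], lY = Y[at(i, j - 1)];
      Y[at(i, j)] = std::max(lM + gap_open + gap_extend,
                             std::max(lY + gap_extend, lX + gap_open + gap_extend));
    }
  }

  // final state: prefer diagonal, then up, then left on ties
  double best = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }
  if (n == 0 && m == 0) { best = 0.0; state = 0; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
    if (state == 0) {
      double target = M[at(i, j)] - sub(ai[i - 1], bj[j - 1]);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (M[at(i, j)] == target) state = 0;
      else if (X[at(i, j)] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      double target = X[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (M[at(i, j)] + gap_open + gap_extend == target) state = 0;
      else if (X[at(i, j)] + gap_extend == target) state = 1;
      else state = 2;
    } else {
      double target = Y[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (M[at(i, j)] + gap_open + gap_extend == target) state = 0;
      else if (X[at(i, j)] + gap_open + gap_extend == target) state = 1;
      else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = best);
}
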
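#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Tie-break in traceback pointers: diagonal beats up (gap in b) beats
// left (gap in a); enforced by strict ">" when filling the DP matrix.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 1 = diag, 2 = up, 3 = left

  for (int i = 1; i <= n; ++i) { F(i, 0) = i * gap; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = j * gap; P(0, j) = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = F(i - 1, j) + gap;
      double l = F(i, j - 1) + gap;
      double best = d;
      int ptr = 1;
      if (u > best) { best = u; ptr = 2; }
      if (l > best) { best = l; ptr = 3; }
      F(i, j) = best;
      P(i, j) = ptr;
    }
  }

  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p;
    if (i > 0 && j > 0) p = P(i, j);
    else p = (i > 0) ? 2 : 3;
    if (p == 1)      { aa += a[i - 1]; bb += b[j - 1]; --i; --j; }
    else if (p == 2) { aa += a[i - 1]; bb += '-';      --i; }
    else             { aa += '-';      bb += b[j - 1]; --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["a_aln"] = aa, _["b_aln"] = bb,
                      _["score"] = F(n, m));
}
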
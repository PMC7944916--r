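#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static int lev_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, sub});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".lev_pair")]]
int lev_pair(std::string a, std::string b) {
  return lev_one(a, b);
}

// [[Rcpp::export(name = ".lev_matrix")]]
IntegerMatrix lev_matrix(CharacterVector A, CharacterVector B) {
  const int n = A.size(), m = B.size();
  IntegerMatrix out(n, m);
  std::vector<std::string> va(n), vb(m);
  for (int i = 0; i < n; ++i) va[i] = Rcpp::as<std::string>(A[i]);
  for (int j = 0; j < m; ++j) vb[j] = Rcpp::as<std::string>(B[j]);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = lev_one(va[i], vb[j]);
  return out;
}
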
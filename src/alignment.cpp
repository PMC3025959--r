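#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and deterministic
// traceback (diagonal > up > left on ties; best cell = first maximum in
// row-major order). Returns enough to compute both identity conventions:
// identity over aligned columns (including internal gaps) and identity over
// the full query length.
// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -2.0,
                  double gap = -3.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  // H: scores, T: traceback (0 stop, 1 diag, 2 up (gap in b), 3 left)
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<signed char> T((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double sdiag = Hprev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup   = Hprev[j] + gap;
      double sleft = Hcur[j - 1] + gap;
      double s = 0.0; signed char t = 0;
      if (sdiag >= sup && sdiag >= sleft && sdiag > 0) { s = sdiag; t = 1; }
      else if (sup >= sleft && sup > 0)               { s = sup;   t = 2; }
      else if (sleft > 0)                             { s = sleft; t = 3; }
      Hcur[j] = s;
      T[(size_t)i * (m + 1) + j] = t;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  int nmatch = 0, ncols = 0;
  int i = bi, j = bj;
  int a_end = bi, b_end = bj;
  while (i > 0 && j > 0) {
    signed char t = T[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    ++ncols;
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++nmatch;
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  double ident = ncols > 0 ? 100.0 * nmatch / ncols : 0.0;
  return List::create(
    _["score"] = best,
    _["aligned_length"] = ncols,
    _["nmatch"] = nmatch,
    _["identity_pct"] = ident,
    _["a_start"] = best > 0 ? i + 1 : NA_INTEGER,
    _["a_end"] = best > 0 ? a_end : NA_INTEGER,
    _["b_start"] = best > 0 ? j + 1 : NA_INTEGER,
    _["b_end"] = best > 0 ? b_end : NA_INTEGER);
}

// Length of the longest exact common substring of a and b.
// [[Rcpp::export(name = ".lcs_length_cpp")]]
int lcs_length_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}

static inline bool wc_pair(char x, char y) {
  return (x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
         (x == 'C' && y == 'G') || (x == 'G' && y == 'C');
}

// Longest intramolecular stem: maximal run of Watson-Crick pairs
// (i, j), (i+1, j-1), ... whose innermost pair encloses a loop of at least
// min_loop unpaired bases.
// [[Rcpp::export(name = ".stem_score_cpp")]]
int stem_score_cpp(std::string s, int min_loop = 3) {
  const int n = s.size();
  if (n < 2) return 0;
  // D[i][j]: run of pairs starting outermost at (i, j) going inward
  std::vector<std::vector<int>> D(n, std::vector<int>(n, 0));
  int best = 0;
  for (int i = n - 2; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      if (wc_pair(s[i], s[j])) {
        int inner = (i + 1 <= j - 1 && i + 1 < n && j - 1 >= 0 && i + 1 < j - 1)
                        ? D[i + 1][j - 1] : 0;
        D[i][j] = inner + 1;
        int cap = (j - i + 1 - min_loop) / 2;  // loop constraint on depth
        int usable = std::min(D[i][j], std::max(cap, 0));
        if (usable > best) best = usable;
      }
    }
  }
  return best;
}
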
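#include <Rcpp.h>
using namespace Rcpp;

// Semi-global edit-distance grid, classic sequential recurrence.
// Symbol codes: text uses 0 for alphabet-external symbols, pattern uses -1,
// so an external symbol never matches anything (not even itself).
//
// D[0, j] = 0; D[i, 0] = i;
// D[i, j] = D[i-1, j-1]                                if T[j-1] == P[i-1]
//         = 1 + min(D[i-1, j], D[i, j-1], D[i-1, j-1]) otherwise.

// [[Rcpp::export(name = ".dp_matrix_c")]]
IntegerMatrix dp_matrix_c(IntegerVector tcodes, IntegerVector pcodes) {
  const int n = tcodes.size(), m = pcodes.size();
  IntegerMatrix D(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) D(i, 0) = i;
  for (int i = 1; i <= m; ++i) {
    const int pc = pcodes[i - 1];
    for (int j = 1; j <= n; ++j) {
      if (tcodes[j - 1] == pc) {
        D(i, j) = D(i - 1, j - 1);
      } else {
        int v = D(i - 1, j);
        if (D(i, j - 1) < v) v = D(i, j - 1);
        if (D(i - 1, j - 1) < v) v = D(i - 1, j - 1);
        D(i, j) = 1 + v;
      }
    }
  }
  return D;
}

// Final row only: O(n) working state.
// [[Rcpp::export(name = ".dp_final_row_c")]]
IntegerVector dp_final_row_c(IntegerVector tcodes, IntegerVector pcodes) {
  const int n = tcodes.size(), m = pcodes.size();
  IntegerVector prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;
  for (int i = 1; i <= m; ++i) {
    const int pc = pcodes[i - 1];
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      if (tcodes[j - 1] == pc) {
        cur[j] = prev[j - 1];
      } else {
        int v = prev[j];
        if (cur[j - 1] < v) v = cur[j - 1];
        if (prev[j - 1] < v) v = prev[j - 1];
        cur[j] = 1 + v;
      }
    }
    std::swap(prev, cur);
  }
  return prev;
}

// Global (standard) Levenshtein distance: D[0, j] = j initialisation.
// Plain code equality; callers encode both strings against a shared table.
// [[Rcpp::export(name = ".levenshtein_c")]]
int levenshtein_c(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const int bc = b[i - 1];
    for (int j = 1; j <= n; ++j) {
      if (a[j - 1] == bc) {
        cur[j] = prev[j - 1];
      } else {
        int v = prev[j];
        if (cur[j - 1] < v) v = cur[j - 1];
        if (prev[j - 1] < v) v = prev[j - 1];
        cur[j] = 1 + v;
      }
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
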
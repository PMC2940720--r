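#include <Rcpp.h>
using namespace Rcpp;

// All-pairs OMES scan over an integer-encoded alignment.
//
// codes: N x L integer matrix, 0 = gap, 1..20 = amino acid.
// For a column pair (i, j) only rows non-gap at both columns contribute
// (n_valid). With joint counts n_xy and marginals c_x, c_y over those rows,
//   score = sum over observed (x,y) of (n_xy - c_x * c_y / n_valid)^2 / n_valid
// i.e. the Fodor variant: the sum runs over amino-acid pairs actually
// observed in the column pair. Pairs with n_valid < min_valid get NA.
//
// Returns a 4-column matrix (i, j, score, n_valid) over all i < j in cols
// (1-based column indices into codes).
// [[Rcpp::export]]
NumericMatrix omes_all_pairs(IntegerMatrix codes, IntegerVector cols,
                             int min_valid) {
  const int n = codes.nrow();
  const int m = cols.size();
  const long npair = (long)m * (m - 1) / 2;
  NumericMatrix out(npair, 4);

  std::vector<int> joint(21 * 21, 0);
  std::vector<int> ci(21, 0), cj(21, 0);
  std::vector<int> touched;
  touched.reserve(64);

  long r = 0;
  for (int a = 0; a < m; ++a) {
    const int col_i = cols[a] - 1;
    for (int b = a + 1; b < m; ++b) {
      const int col_j = cols[b] - 1;
      int nv = 0;
      touched.clear();
      std::fill(ci.begin(), ci.end(), 0);
      std::fill(cj.begin(), cj.end(), 0);
      for (int s = 0; s < n; ++s) {
        const int x = codes(s, col_i);
        const int y = codes(s, col_j);
        if (x == 0 || y == 0) continue;
        ++nv;
        ++ci[x];
        ++cj[y];
        const int cell = x * 21 + y;
        if (joint[cell]++ == 0) touched.push_back(cell);
      }
      double score = NA_REAL;
      if (nv >= min_valid && nv > 0) {
        score = 0.0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int cell = touched[t];
          const double obs = joint[cell];
          const double exp = (double)ci[cell / 21] * cj[cell % 21] / nv;
          score += (obs - exp) * (obs - exp) / nv;
        }
      }
      for (size_t t = 0; t < touched.size(); ++t) joint[touched[t]] = 0;
      out(r, 0) = cols[a];
      out(r, 1) = cols[b];
      out(r, 2) = score;
      out(r, 3) = nv;
      ++r;
    }
  }
  return out;
}
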
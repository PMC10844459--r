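#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping over integer code sequences.
// Local cost |a_i - b_j|, steps {(1,0),(0,1),(1,1)}, full-path cumulative sum.
// [[Rcpp::export(name = ".dtwDistanceC")]]
double dtwDistanceC(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw_distance requires non-empty sequences");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double cost = std::abs((double)a[i - 1] - (double)b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Longest common subsequence length between two word sequences (as integer
// ids). Used for minimum-edit word alignment where a substitution costs an
// insertion plus a deletion.
// [[Rcpp::export(name = ".lcsLengthC")]]
int lcsLengthC(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return prev[m];
}
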
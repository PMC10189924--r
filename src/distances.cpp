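// Batched slide-to-slide distances over stacked patch features.
//
// median_of_min is directional: entry (i, j) is the median over patches a
// of slide i of min_b ||a - b|| over patches b of slide j. The "lower"
// median convention returns the lower-middle order statistic for even
// counts, so the value is always an attained min-distance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double median_of(std::vector<double>& v, bool lower) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (lower || n % 2 == 1) return v[(n - 1) / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export]]
arma::mat cpp_slide_distances(const arma::mat& X, const arma::ivec& starts,
                              const arma::ivec& counts, bool lower_median) {
  const int ns = starts.n_elem;
  vec sq = sum(square(X), 1);
  mat D(ns, ns, fill::zeros);
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      const int ai = starts[i], ni = counts[i];
      const int aj = starts[j], nj = counts[j];
      mat cross = X.rows(ai, ai + ni - 1) * X.rows(aj, aj + nj - 1).t();
      mat d2(ni, nj);
      for (int c = 0; c < nj; ++c)
        for (int r = 0; r < ni; ++r) {
          double v = sq[ai + r] + sq[aj + c] - 2.0 * cross(r, c);
          d2(r, c) = v > 0 ? std::sqrt(v) : 0.0;
        }
      std::vector<double> mins_i(ni), mins_j(nj);
      for (int r = 0; r < ni; ++r) mins_i[r] = d2.row(r).min();
      for (int c = 0; c < nj; ++c) mins_j[c] = d2.col(c).min();
      D(i, j) = median_of(mins_i, lower_median);
      D(j, i) = median_of(mins_j, lower_median);
    }
  }
  return D;
}
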
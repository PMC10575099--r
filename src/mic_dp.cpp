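#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Optimal-column dynamic program for the maximal information coefficient.
//
// Points are assumed sorted by the column variable; `ybin` gives each
// point's (1-based) row index under a fixed row partition.  Cuts between
// adjacent points are allowed only where the column variable changes
// (`cut_ok[i]` refers to the boundary after point i+1, 0-based).  Returns,
// for each column count l = 1..cmax, the maximum mutual information (bits)
// over partitions of the column axis into at most l contiguous intervals.
//
// I(partition) decomposes additively over column parts:
//   sum_part sum_row (n_pr/n) * log2(n_pr * n / (n_p * n_row)).
// [[Rcpp::export]]
NumericVector mic_dp(IntegerVector ybin, int r, int cmax, LogicalVector cut_ok) {
  int n = ybin.size();
  if (n < 2 || r < 1 || cmax < 1) stop("mic_dp: invalid sizes");

  // Boundary positions: 0, allowed internal cuts, n.
  std::vector<int> pos;
  pos.push_back(0);
  for (int i = 0; i + 1 < n; ++i) if (cut_ok[i]) pos.push_back(i + 1);
  pos.push_back(n);
  int m = pos.size();

  // Row totals and cumulative row counts at each boundary.
  std::vector<double> nrow(r, 0.0);
  for (int i = 0; i < n; ++i) nrow[ybin[i] - 1] += 1.0;
  std::vector<double> cum((size_t)m * r, 0.0);
  {
    std::vector<double> acc(r, 0.0);
    int pi = 0;
    for (int i = 0; i <= n; ++i) {
      if (pos[pi] == i) {
        for (int q = 0; q < r; ++q) cum[(size_t)pi * r + q] = acc[q];
        ++pi;
        if (pi >= m) break;
      }
      if (i < n) acc[ybin[i] - 1] += 1.0;
    }
  }

  const double nn = (double)n;
  const double log2e = 1.0 / std::log(2.0);
  // Cache contrib(j, i) -- the MI contribution of a column part spanning
  // boundaries j..i -- since the DP revisits it for every column count.
  std::vector<double> ctr((size_t)m * m, 0.0);
  for (int j = 0; j < m; ++j) {
    for (int i = j + 1; i < m; ++i) {
      double np = pos[i] - pos[j];
      double s = 0.0;
      for (int q = 0; q < r; ++q) {
        double c = cum[(size_t)i * r + q] - cum[(size_t)j * r + q];
        if (c > 0.0 && nrow[q] > 0.0)
          s += (c / nn) * std::log(c * nn / (np * nrow[q])) * log2e;
      }
      ctr[(size_t)j * m + i] = s;
    }
  }

  // F[l][i]: best MI over <= l parts covering the prefix up to boundary i.
  NumericVector best(cmax);
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < m; ++i) prev[i] = ctr[(size_t)0 * m + i];
  best[0] = prev[m - 1];
  for (int l = 2; l <= cmax; ++l) {
    for (int i = 0; i < m; ++i) {
      double b = prev[i];  // fewer parts allowed
      for (int j = 1; j < i; ++j) {
        double v = prev[j] + ctr[(size_t)j * m + i];
        if (v > b) b = v;
      }
      cur[i] = b;
    }
    std::swap(prev, cur);
    best[l - 1] = prev[m - 1];
  }
  return best;
}
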
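// Classical dynamic time warping with absolute-difference local cost,
// steps {(1,0),(0,1),(1,1)} and an optional Sakoe-Chiba band scaled to
// the length ratio. Ties are broken deterministically: diagonal first,
// then the step consuming the first sequence.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// band_radius < 0 means no band
// [[Rcpp::export]]
Rcpp::List cpp_dtw(const arma::vec& a, const arma::vec& b, int band_radius) {
  const int n = a.n_elem, m = b.n_elem;
  const double INF = std::numeric_limits<double>::infinity();

  // per-row window [lo[i], hi[i]] around the scaled diagonal
  std::vector<int> lo(n), hi(n);
  for (int i = 0; i < n; ++i) {
    if (band_radius < 0) { lo[i] = 0; hi[i] = m - 1; continue; }
    const double c = (n == 1) ? (m - 1) / 2.0
                              : (double)(m - 1) * i / (double)(n - 1);
    lo[i] = std::max(0, (int)std::ceil(c - band_radius));
    hi[i] = std::min(m - 1, (int)std::floor(c + band_radius));
    if (lo[i] > hi[i]) Rcpp::stop("band too narrow to connect the corners");
  }
  int width = 0;
  for (int i = 0; i < n; ++i) width = std::max(width, hi[i] - lo[i] + 1);

  // step codes: 0 origin, 1 diagonal, 2 consume a (i-1,j), 3 consume b (i,j-1)
  std::vector<unsigned char> step((size_t)n * width, 0);
  std::vector<double> prev(width, INF), cur(width, INF);

  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      const double local = std::fabs(a[i] - b[j]);
      double best = INF;
      unsigned char sc = 0;
      if (i == 0 && j == 0) {
        best = 0.0; sc = 0;
      } else {
        if (i > 0 && j > 0 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
          const double v = prev[j - 1 - lo[i - 1]];
          if (v < best) { best = v; sc = 1; }
        }
        if (i > 0 && j >= lo[i - 1] && j <= hi[i - 1]) {
          const double v = prev[j - lo[i - 1]];
          if (v < best) { best = v; sc = 2; }
        }
        if (j > lo[i]) {
          const double v = cur[j - 1 - lo[i]];
          if (v < best) { best = v; sc = 3; }
        }
      }
      cur[j - lo[i]] = local + best;
      step[(size_t)i * width + (j - lo[i])] = sc;
    }
    std::swap(prev, cur);
  }

  const double total = prev[m - 1 - lo[n - 1]];
  if (!std::isfinite(total))
    Rcpp::stop("band too narrow to connect the corners");

  // traceback
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    const unsigned char sc = step[(size_t)i * width + (j - lo[i])];
    if (i == 0 && j == 0) break;
    if (sc == 1) { --i; --j; }
    else if (sc == 2) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return Rcpp::List::create(Rcpp::Named("cost") = total,
                            Rcpp::Named("i") = Rcpp::wrap(pi),
                            Rcpp::Named("j") = Rcpp::wrap(pj));
}
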
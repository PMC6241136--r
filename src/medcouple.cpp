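#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Medcouple skewness statistic, brute-force O(n^2) kernel enumeration.
//
// Convention (matches the pure-R oracle in R/medcouple.R operation for
// operation): x is sorted ascending; m is the sample median (mean of the two
// middle order statistics for even n); the kernel
//   h(x_i, x_j) = ((x_j - m) - (m - x_i)) / (x_j - x_i)
// is evaluated over every pair of DISTINCT observations with x_i <= m <= x_j.
// When x_i == x_j (both equal to m), with p observations tied to the median
// and a, b the 1-based positions of the pair within that tied block,
// h = sign(a + b - 1 - p). The self-pair of a single median observation is
// excluded. The statistic is the median of all kernel values.
//
// The median of the kernel values is computed by selecting the same order
// statistics R's median() uses, so the result is bit-identical to the R
// reference on every input. Buffers are reused across bootstrap replicates.

static double mc_core(std::vector<double> &x, std::vector<double> &h) {
  const int n = static_cast<int>(x.size());
  std::sort(x.begin(), x.end());

  double m;
  if (n % 2 == 1) {
    m = x[(n - 1) / 2];
  } else {
    m = (x[n / 2 - 1] + x[n / 2]) / 2.0;
  }

  int lo_end = 0;              // one past last index with x <= m
  while (lo_end < n && x[lo_end] <= m) ++lo_end;
  int up_start = n;            // first index with x >= m
  while (up_start > 0 && x[up_start - 1] >= m) --up_start;

  int tie_start = up_start, tie_end = lo_end;
  int p = tie_end - tie_start; // observations equal to m
  if (p < 0) p = 0;

  h.clear();
  for (int i = 0; i < lo_end; ++i) {
    for (int j = up_start; j < n; ++j) {
      if (i == j) continue;    // same observation
      if (x[i] == x[j]) {      // both equal to m: tie kernel
        int a = i - tie_start + 1;
        int b = j - tie_start + 1;
        int s = a + b - 1 - p;
        h.push_back(s > 0 ? 1.0 : (s < 0 ? -1.0 : 0.0));
      } else {
        h.push_back(((x[j] - m) - (m - x[i])) / (x[j] - x[i]));
      }
    }
  }
  const size_t nh = h.size();
  if (nh == 0) return 0.0;     // cannot occur for n >= 3, defensive

  if (nh % 2 == 1) {
    std::nth_element(h.begin(), h.begin() + nh / 2, h.end());
    return h[nh / 2];
  }
  std::nth_element(h.begin(), h.begin() + nh / 2 - 1, h.end());
  const double lo = h[nh / 2 - 1];
  const double hi = *std::min_element(h.begin() + nh / 2, h.end());
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
double medcouple_cpp(Rcpp::NumericVector x_in) {
  const int n = static_cast<int>(x_in.size());
  if (n < 3) Rcpp::stop("medcouple requires at least 3 observations");
  std::vector<double> x(x_in.begin(), x_in.end());
  std::vector<double> h;
  h.reserve(static_cast<size_t>(n / 2 + 1) * (n / 2 + 1));
  return mc_core(x, h);
}

// Medcouple of each bootstrap resample; idx is an n x B matrix of 1-based
// indices into x (drawn in R so resampling follows R's RNG).
// [[Rcpp::export]]
Rcpp::NumericVector medcouple_boot_cpp(Rcpp::NumericVector x_in,
                                       Rcpp::IntegerMatrix idx) {
  const int n = idx.nrow(), B = idx.ncol();
  if (n < 3) Rcpp::stop("medcouple requires at least 3 observations");
  Rcpp::NumericVector out(B);
  std::vector<double> x(n);
  std::vector<double> h;
  h.reserve(static_cast<size_t>(n / 2 + 1) * (n / 2 + 1));
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) x[i] = x_in[idx(i, b) - 1];
    out[b] = mc_core(x, h);
  }
  return out;
}
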
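#include <Rcpp.h>
using namespace Rcpp;

// Hartigan-Hartigan dip statistic.
//
// The dip is the smallest d such that some unimodal CDF G (convex below its
// mode, concave above, an atom allowed at the mode) stays within d of the
// empirical CDF in sup norm.  For a mode placed at a data point m this is a
// convex/concave band-interpolation feasibility problem whose minimal d has a
// closed form over point triples; minimising over data-point modes is exact,
// because any fit with a mode strictly between two observations is dominated
// by a fit whose mode sits on one of them (bending at the neighbouring data
// point never costs more).  Ties are collapsed so the ECDF bands carry the
// full jump mass.  Complexity O(u^3) for u unique values.

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  int n = xs.size();
  if (n < 1) stop("empty sample");
  for (int i = 1; i < n; ++i)
    if (xs[i] < xs[i - 1]) stop("input must be sorted");

  std::vector<double> x, ym, yp;  // unique values, ECDF left/right limits
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    x.push_back(xs[i]);
    ym.push_back((double)i / n);
    yp.push_back((double)j / n);
    i = j;
  }
  int m = (int)x.size();
  double base = 1.0 / (2.0 * n);
  if (m == 1) return base;

  std::vector<double> jump(m);
  for (int j = 0; j < m; ++j) jump[j] = yp[j] - ym[j];

  // devL[k]: half the largest convex-band violation over points 0..k when the
  // mode sits at k (triples use lower ECDF limits as chord endpoints, upper
  // limits at interior points; interior jumps below the mode must be covered).
  std::vector<double> devL(m, 0.0), devR(m, 0.0);
  {
    double tri = 0.0, jm = 0.0;
    for (int k = 0; k < m; ++k) {
      for (int jj = 1; jj < k; ++jj) {
        for (int ii = 0; ii < jj; ++ii) {
          double interp =
              ym[ii] + (ym[k] - ym[ii]) * (x[jj] - x[ii]) / (x[k] - x[ii]);
          double v = yp[jj] - interp;
          if (v > tri) tri = v;
        }
      }
      devL[k] = 0.5 * std::max(tri, jm);
      if (jump[k] > jm) jm = jump[k];
    }
  }
  {
    double tri = 0.0, jm = 0.0;
    for (int k = m - 1; k >= 0; --k) {
      for (int jj = k + 1; jj < m - 1; ++jj) {
        for (int kk = jj + 1; kk < m; ++kk) {
          double interp =
              yp[k] + (yp[kk] - yp[k]) * (x[jj] - x[k]) / (x[kk] - x[k]);
          double v = interp - ym[jj];
          if (v > tri) tri = v;
        }
      }
      devR[k] = 0.5 * std::max(tri, jm);
      if (jump[k] > jm) jm = jump[k];
    }
  }

  double best = R_PosInf;
  for (int k = 0; k < m; ++k) {
    double d = std::max(devL[k], devR[k]);
    if (d < best) best = d;
  }
  return std::max(base, best);
}

// Null distribution of the dip for samples of size n from U(0,1); uses R's
// RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int reps) {
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    NumericVector u = runif(n);
    std::sort(u.begin(), u.end());
    out[r] = dip_stat_cpp(u);
  }
  return out;
}
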
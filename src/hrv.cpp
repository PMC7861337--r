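#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy (Pincus). Chebyshev distance, self-matches included,
// ApEn = Phi(m) - Phi(m+1) with Phi the mean log of match fractions.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  double phi[2] = {0.0, 0.0};
  for (int step = 0; step < 2; ++step) {
    int mm = m + step;
    int nv = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nv; ++i) {
      int cnt = 0;
      for (int j = 0; j < nv; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dd = std::fabs(x[i + k] - x[j + k]);
          if (dd > d) d = dd;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)nv);
    }
    phi[step] = acc / (double)nv;
  }
  return phi[0] - phi[1];
}

// Nearest-neighbour index for each embedded point, excluding a Theiler
// window of +/- theiler samples around the reference (Euclidean distance on
// delay embedding of dimension dim with lag `lag`).
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericVector x, int dim, int lag, int theiler) {
  int n = x.size();
  int nv = n - (dim - 1) * lag;
  IntegerVector out(nv, NA_INTEGER);
  for (int i = 0; i < nv; ++i) {
    double best = R_PosInf;
    int bi = -1;
    for (int j = 0; j < nv; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double dd = x[i + k * lag] - x[j + k * lag];
        d += dd * dd;
      }
      if (d < best) { best = d; bi = j; }
    }
    if (bi >= 0) out[i] = bi + 1; // 1-based
  }
  return out;
}

// Mean log divergence between trajectories and their nearest neighbours at
// forward steps 1..n_steps (Rosenstein). Pairs are dropped once either
// trajectory runs off the end. Returns n_steps values (NA when no pair).
// [[Rcpp::export]]
NumericVector rosenstein_divergence_cpp(NumericVector x, IntegerVector nn,
                                        int n_steps) {
  int nv = nn.size();
  NumericVector out(n_steps, NA_REAL);
  for (int s = 1; s <= n_steps; ++s) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < nv; ++i) {
      if (nn[i] == NA_INTEGER) continue;
      int j = nn[i] - 1;
      if (i + s >= nv || j + s >= nv) continue;
      double d = std::fabs(x[i + s] - x[j + s]);
      if (d > 0.0) { acc += std::log(d); ++cnt; }
    }
    if (cnt > 0) out[s - 1] = acc / (double)cnt;
  }
  return out;
}
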
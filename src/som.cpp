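#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online SOM training. Prototypes are updated in place on a copy and
// returned. All randomness (sample presentation order) is decided in R so
// that results are reproducible from the R seed alone.
//
// proto:   d x p initial prototype matrix
// x:       N x p data matrix
// order:   0-based row indices into x, one per presentation step
// gridpos: d x 2 unit coordinates on the lattice (row, col)
// alpha0 / sigma0: initial learning rate and neighbourhood width
// lambda_alpha / lambda_sigma: exponential decay time constants (in steps)
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix proto, NumericMatrix x,
                            IntegerVector order, NumericMatrix gridpos,
                            double alpha0, double sigma0,
                            double lambda_alpha, double lambda_sigma) {
  const int d = proto.nrow(), p = proto.ncol(), T = order.size();
  NumericMatrix w = clone(proto);

  for (int t = 0; t < T; ++t) {
    const int r = order[t];
    // best matching unit: strict < keeps the lowest linear index on ties
    int bmu = 0;
    double best = R_PosInf;
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = w(i, j) - x(r, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = i; }
    }
    const double alpha = alpha0 * std::exp(-(double)t / lambda_alpha);
    const double sigma = sigma0 * std::exp(-(double)t / lambda_sigma);
    const double denom = 2.0 * sigma * sigma;
    const double br = gridpos(bmu, 0), bc = gridpos(bmu, 1);
    for (int i = 0; i < d; ++i) {
      const double dr = gridpos(i, 0) - br, dc = gridpos(i, 1) - bc;
      const double h = std::exp(-(dr * dr + dc * dc) / denom);
      const double ah = alpha * h;
      if (ah < 1e-12) continue;
      for (int j = 0; j < p; ++j)
        w(i, j) += ah * (x(r, j) - w(i, j));
    }
  }
  return w;
}

// Best matching unit and distance for each row of x.
// Returns a list with 1-based unit indices and Euclidean distances.
// [[Rcpp::export]]
List som_bmu_cpp(NumericMatrix proto, NumericMatrix x) {
  const int d = proto.nrow(), p = proto.ncol(), N = x.nrow();
  IntegerVector unit(N);
  NumericVector dist(N);
  for (int r = 0; r < N; ++r) {
    int bmu = 0;
    double best = R_PosInf;
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = proto(i, j) - x(r, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = i; }
    }
    unit[r] = bmu + 1;
    dist[r] = std::sqrt(best);
  }
  return List::create(_["unit"] = unit, _["distance"] = dist);
}
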
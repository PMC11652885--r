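// Sequential minimal optimisation for the soft-margin C-SVC dual
// (LIBSVM-style maximal-violating-pair selection). Hot loop of the
// SVM filter's hyperparameter search; the R wrapper owns standardisation,
// kernels and model assembly.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".smo_cpp")]]
List smo_cpp(NumericMatrix K, NumericVector y, double C,
             double eps = 1e-3, int max_iter = 200000) {
  const int n = y.size();
  NumericVector alpha(n), grad(n, -1.0);
  std::vector<double> Q(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      Q[static_cast<size_t>(i) * n + j] = K(j, i) * y[i] * y[j];

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      double yg = -y[t] * grad[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && yg > gmax) { gmax = yg; i = t; }
      if (low && yg < gmin) { gmin = yg; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    double quad = Q[static_cast<size_t>(i) * n + i] +
                  Q[static_cast<size_t>(j) * n + j] -
                  2.0 * y[i] * y[j] * Q[static_cast<size_t>(i) * n + j];
    if (quad <= 0) quad = 1e-12;
    double delta = (gmax - gmin) / quad;
    double ai = alpha[i], aj = alpha[j];
    if (y[i] > 0) delta = std::min(delta, C - ai);
    else          delta = std::min(delta, ai);
    if (y[j] > 0) delta = std::min(delta, aj);
    else          delta = std::min(delta, C - aj);
    alpha[i] = ai + y[i] * delta;
    alpha[j] = aj - y[j] * delta;
    const double di = alpha[i] - ai, dj = alpha[j] - aj;
    const double *qi = &Q[static_cast<size_t>(i) * n];
    const double *qj = &Q[static_cast<size_t>(j) * n];
    for (int t = 0; t < n; ++t) grad[t] += qi[t] * di + qj[t] * dj;
  }

  // bias from free support vectors, else midpoint of the KKT interval
  double bsum = 0.0; int bfree = 0;
  double up_min = 1e30, low_max = -1e30;
  for (int t = 0; t < n; ++t) {
    double yg = -y[t] * grad[t];
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) { bsum += yg; ++bfree; }
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up && yg < up_min) up_min = yg;
    if (low && yg > low_max) low_max = yg;
  }
  double b = bfree > 0 ? bsum / bfree : (low_max + up_min) / 2.0;
  return List::create(_["alpha"] = alpha, _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
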
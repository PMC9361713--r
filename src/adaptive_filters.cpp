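#include <Rcpp.h>
using namespace Rcpp;

// Sample-recursive adaptive filters. The tap-delay vector at sample i is
// x_i = [ref[i], ref[i-1], ..., ref[i-order+1]] with zero-padded history;
// weights start at zero. All return the filter output y (error = d - y is
// formed on the R side).

// [[Rcpp::export]]
List lms_filter_cpp(NumericVector d, NumericVector ref, int order,
                    double mu) {
  int n = d.size();
  NumericVector y(n);
  std::vector<double> w(order, 0.0);
  for (int i = 0; i < n; ++i) {
    double yi = 0.0;
    int kmax = std::min(order, i + 1);
    for (int k = 0; k < kmax; ++k) yi += w[k] * ref[i - k];
    y[i] = yi;
    double e = d[i] - yi;
    for (int k = 0; k < kmax; ++k) w[k] += 2.0 * mu * e * ref[i - k];
  }
  return List::create(Named("y") = y,
                      Named("w") = NumericVector(w.begin(), w.end()));
}

// [[Rcpp::export]]
List nlms_filter_cpp(NumericVector d, NumericVector ref, int order,
                     double mu, double eps) {
  int n = d.size();
  NumericVector y(n);
  std::vector<double> w(order, 0.0);
  for (int i = 0; i < n; ++i) {
    double yi = 0.0, p = 0.0;
    int kmax = std::min(order, i + 1);
    for (int k = 0; k < kmax; ++k) {
      double xk = ref[i - k];
      yi += w[k] * xk;
      p += xk * xk;
    }
    y[i] = yi;
    double e = d[i] - yi;
    double g = mu * e / (eps + p);
    for (int k = 0; k < kmax; ++k) w[k] += g * ref[i - k];
  }
  return List::create(Named("y") = y,
                      Named("w") = NumericVector(w.begin(), w.end()));
}

// [[Rcpp::export]]
List rls_filter_cpp(NumericVector d, NumericVector ref, int order,
                    double lambda, double delta) {
  int n = d.size();
  NumericVector y(n);
  std::vector<double> w(order, 0.0);
  std::vector<double> P(order * order, 0.0);   // inverse correlation
  for (int k = 0; k < order; ++k) P[k * order + k] = 1.0 / delta;
  std::vector<double> x(order, 0.0), Px(order), g(order);
  double inv_lambda = 1.0 / lambda;
  for (int i = 0; i < n; ++i) {
    for (int k = order - 1; k > 0; --k) x[k] = x[k - 1];
    x[0] = ref[i];
    // Px = P x ; denom = lambda + x' P x
    double denom = lambda;
    for (int r = 0; r < order; ++r) {
      double acc = 0.0;
      for (int c = 0; c < order; ++c) acc += P[r * order + c] * x[c];
      Px[r] = acc;
      denom += x[r] * acc;
    }
    if (!std::isfinite(denom) || denom <= 0.0)
      stop("RLS numeric breakdown at sample %d (non-finite gain)", i + 1);
    double yi = 0.0;
    for (int k = 0; k < order; ++k) yi += w[k] * x[k];
    y[i] = yi;
    double e = d[i] - yi;
    for (int k = 0; k < order; ++k) {
      g[k] = Px[k] / denom;
      w[k] += g[k] * e;
    }
    // P = (P - g (x'P)) / lambda ; x'P = Px' by symmetry of P.
    // Re-symmetrize to stop floating-point asymmetry from destroying
    // positive definiteness over long runs.
    for (int r = 0; r < order; ++r)
      for (int c = 0; c < order; ++c)
        P[r * order + c] = (P[r * order + c] - g[r] * Px[c]) * inv_lambda;
    for (int r = 0; r < order; ++r)
      for (int c = r + 1; c < order; ++c) {
        double v = 0.5 * (P[r * order + c] + P[c * order + r]);
        P[r * order + c] = v;
        P[c * order + r] = v;
      }
  }
  return List::create(Named("y") = y, Named("w") = NumericVector(w.begin(), w.end()));
}

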
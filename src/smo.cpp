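#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Soft-margin SVM dual solver over a precomputed kernel.
//
// Minimizes 1/2 a' Q a - e' a with Q_ij = y_i y_j K_ij, subject to
// 0 <= a_i <= C and y' a = 0, by sequential minimal optimization.
// Working sets are chosen by the maximal-violating-pair rule for i and
// second-order gain for j; terminates when the KKT violation gap drops
// below eps.
//
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double eps, int max_iter) {
  const int n = K.nrow();
  const double tau = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = Qa - e

  int iter = 0;
  double gap = R_PosInf;
  while (iter < max_iter) {
    // i: maximal violation among I_up; track the I_low minimum for the
    // stopping gap
    int i = -1;
    double Gmax = R_NegInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) Gmin = v;
    }
    gap = Gmax - Gmin;
    if (i < 0 || gap < eps) break;

    // j: largest second-order decrease -b^2 / a among violating I_low
    int j = -1;
    double best = R_PosInf;
    const double Kii = K(i, i);
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      const double v = -y[t] * G[t];
      const double b = Gmax - v;
      if (b <= 0) continue;
      double a = Kii + K(t, t) - 2.0 * K(i, t);
      if (a <= 0) a = tau;
      const double score = -(b * b) / a;
      if (score < best) { best = score; j = t; }
    }
    if (j < 0) break;

    const double b = Gmax - (-y[j] * G[j]);
    double quad = Kii + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0.0) quad = tau;
    double d = b / quad;

    // box constraints along the direction u_i = y_i, u_j = -y_j
    double dmax_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double dmax_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (d > dmax_i) d = dmax_i;
    if (d > dmax_j) d = dmax_j;

    alpha[i] += y[i] * d;
    alpha[j] -= y[j] * d;
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > C) alpha[j] = C;

    for (int t = 0; t < n; ++t)
      G[t] += y[t] * d * (K(t, i) - K(t, j));

    ++iter;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["converged"] = (gap < eps));
}
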
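// Sequential minimal optimization for linear-kernel nu-support-vector
// regression, specialized for deconvolution workloads where the same
// signature (hence the same kernel matrix Q = X X^T) is reused across
// thousands of mixtures and permutations. Solves the standard nu-SVR
// dual (Chang & Lin):
//
//   min_{alpha, alpha*}  0.5 (a - a*)' Q (a - a*) - y'(a - a*)
//   s.t. 0 <= a_i, a*_i <= C,  e'(a - a*) = 0,  e'(a + a*) = C nu l
//
// using SMO with second-order working-set selection within each of
// the two blocks (pair updates preserve both equality constraints).
// Returns beta = alpha - alpha*; the weight vector over signature
// columns is w = X' beta.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".nusvr_smo")]]
NumericVector nusvr_smo(NumericMatrix Q, NumericVector y, double nu,
                        double cost, double tol = 1e-3,
                        int max_iter = 100000) {
  const int l = y.size();
  if (Q.nrow() != l || Q.ncol() != l)
    stop("Q must be l x l");
  const double C = cost;
  const double* q = REAL(Q);

  std::vector<double> alpha(l), alphastar(l), beta(l, 0.0), G(l),
      qd(l);
  for (int i = 0; i < l; ++i) qd[i] = q[(size_t)i * l + i];
  // libsvm-style initialization: fill C*nu*l/2 into both blocks
  double remaining = C * nu * l / 2.0;
  for (int i = 0; i < l; ++i) {
    double a = std::min(remaining, C);
    alpha[i] = alphastar[i] = a;
    remaining -= a;
  }
  for (int i = 0; i < l; ++i) G[i] = -y[i];  // beta = 0

  const double TAU = 1e-12;
  for (int iter = 0; iter < max_iter; ++iter) {
    // one pass: extrema for both blocks
    int iA = -1, iB = -1;
    double GminA = R_PosInf, GmaxA = R_NegInf;  // block alpha
    double GmaxB = R_NegInf, GminB = R_PosInf;  // block alpha*
    for (int t = 0; t < l; ++t) {
      const double g = G[t];
      if (alpha[t] < C && g < GminA) { GminA = g; iA = t; }
      if (alpha[t] > 0 && g > GmaxA) { GmaxA = g; }
      if (alphastar[t] < C && g > GmaxB) { GmaxB = g; iB = t; }
      if (alphastar[t] > 0 && g < GminB) { GminB = g; }
    }
    const double violA = (iA >= 0) ? GmaxA - GminA : R_NegInf;
    const double violB = (iB >= 0) ? GmaxB - GminB : R_NegInf;
    if (std::max(violA, violB) < tol) break;

    if (violA >= violB) {
      const double* qi = q + (size_t)iA * l;  // column iA (symmetric)
      const double qii = qd[iA];
      int jA = -1;
      double best = R_PosInf;
      for (int t = 0; t < l; ++t) {
        if (alpha[t] <= 0) continue;
        const double diff = G[t] - GminA;
        if (diff <= 0) continue;
        double quad = qii + qd[t] - 2.0 * qi[t];
        if (quad <= TAU) quad = TAU;
        const double obj = -(diff * diff) / quad;
        if (obj < best) { best = obj; jA = t; }
      }
      if (jA < 0) break;
      double quad = qii + qd[jA] - 2.0 * qi[jA];
      if (quad <= TAU) quad = TAU;
      double step = (G[jA] - GminA) / quad;
      step = std::min(step, C - alpha[iA]);
      step = std::min(step, alpha[jA]);
      alpha[iA] += step; alpha[jA] -= step;
      beta[iA] += step; beta[jA] -= step;
      const double* qj = q + (size_t)jA * l;
      for (int t = 0; t < l; ++t) G[t] += step * (qi[t] - qj[t]);
    } else {
      const double* qi = q + (size_t)iB * l;
      const double qii = qd[iB];
      int jB = -1;
      double best = R_PosInf;
      for (int t = 0; t < l; ++t) {
        if (alphastar[t] <= 0) continue;
        const double diff = GmaxB - G[t];
        if (diff <= 0) continue;
        double quad = qii + qd[t] - 2.0 * qi[t];
        if (quad <= TAU) quad = TAU;
        const double obj = -(diff * diff) / quad;
        if (obj < best) { best = obj; jB = t; }
      }
      if (jB < 0) break;
      double quad = qii + qd[jB] - 2.0 * qi[jB];
      if (quad <= TAU) quad = TAU;
      double step = (GmaxB - G[jB]) / quad;
      step = std::min(step, C - alphastar[iB]);
      step = std::min(step, alphastar[jB]);
      alphastar[iB] += step; alphastar[jB] -= step;
      beta[iB] -= step; beta[jB] += step;
      const double* qj = q + (size_t)jB * l;
      for (int t = 0; t < l; ++t) G[t] -= step * (qi[t] - qj[t]);
    }
  }
  return wrap(beta);
}
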
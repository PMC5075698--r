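#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood contributions of the shared random-effects joint
// model, one per subject, with the bivariate random effect integrated out
// on a fixed (pseudo-adaptive) Gauss-Hermite grid.
//
// Per subject i and grid node q (random effect b = (b0g, b1g)):
//   longitudinal: Gaussian, via per-subject sufficient statistics;
//   survival:     delta * log h(T|b) - H(T|b) with
//                 h(t|b) = h0(t) exp(gamma u + alpha (m0 + m1 t)),
//                 m0 = beta0 + b0, m1 = beta1 + b1;
//   prior:        bivariate normal density of b under D;
//   logw:         node log-weight (Gauss-Hermite weights, the e^{z'z}
//                 correction and the 2|L_i| Jacobian), precomputed in R.
// The cumulative hazard uses fixed-order Gauss-Legendre points sgl/wgl on
// [0, T_i] for the Weibull baseline, and a closed form per interval for the
// piecewise-constant baseline. Node sums use log-sum-exp.
//
// baseline_type: 0 = Weibull (bl[0] = log scale, bl[1] = log shape),
//                1 = piecewise-constant (bl = interval log-hazards,
//                    knots = interior cut points, ascending).
// [[Rcpp::export]]
NumericVector joint_subject_logliks_cpp(
    double beta0, double beta1, double sigma2,
    NumericMatrix Dmat, double alpha, double gamma_,
    int baseline_type, NumericVector bl, NumericVector knots,
    NumericVector T, IntegerVector delta, NumericVector u,
    NumericVector ssn, NumericVector ssS1, NumericVector ssS2,
    NumericVector ssZy1, NumericVector ssZy2, NumericVector ssyy,
    NumericMatrix b0g, NumericMatrix b1g, NumericMatrix logw,
    NumericMatrix sgl, NumericMatrix wgl) {

  const int n = T.size();
  const int G = b0g.ncol();
  const int S = sgl.ncol();
  NumericVector out(n);

  const double d11 = Dmat(0, 0), d12 = Dmat(0, 1), d22 = Dmat(1, 1);
  const double detD = d11 * d22 - d12 * d12;
  const double ldetD = std::log(detD);
  const double i11 = d22 / detD, i12 = -d12 / detD, i22 = d11 / detD;
  const double log2pi = std::log(2.0 * M_PI);
  const double lsig = std::log(2.0 * M_PI * sigma2);

  // Weibull baseline pieces that do not depend on the node
  double lw = 0.0, shape = 1.0;
  std::vector<double> h0s;
  if (baseline_type == 0) {
    lw = bl[0];
    shape = std::exp(bl[1]);
    h0s.resize((size_t)n * S);
    for (int i = 0; i < n; ++i) {
      for (int s = 0; s < S; ++s) {
        double sv = sgl(i, s);
        h0s[(size_t)i * S + s] =
          sv > 0.0 ? std::exp(lw) * shape * std::pow(sv, shape - 1.0) : 0.0;
      }
    }
  }
  const int J = baseline_type == 1 ? bl.size() : 0;

  std::vector<double> node_ll(G);
  for (int i = 0; i < n; ++i) {
    const double Ti = T[i];
    const double gu = gamma_ * u[i];
    // piecewise interval for log h0(T)
    int jT = 0;
    if (baseline_type == 1 && delta[i] == 1) {
      while (jT < J - 1 && Ti > knots[jT]) ++jT;
    }
    double best = R_NegInf;
    for (int q = 0; q < G; ++q) {
      const double b0 = b0g(i, q), b1 = b1g(i, q);
      const double m0 = beta0 + b0, m1 = beta1 + b1;
      // longitudinal
      double ll = 0.0;
      if (ssn[i] > 0) {
        double rss = ssyy[i] - 2.0 * (m0 * ssZy1[i] + m1 * ssZy2[i]) +
          m0 * m0 * ssn[i] + 2.0 * m0 * m1 * ssS1[i] + m1 * m1 * ssS2[i];
        ll += -0.5 * ssn[i] * lsig - 0.5 * rss / sigma2;
      }
      // survival
      if (Ti > 0.0) {
        const double am1 = alpha * m1;
        const double lin = gu + alpha * m0;
        double cumh = 0.0;
        if (baseline_type == 0) {
          double acc = 0.0;
          const size_t off = (size_t)i * S;
          for (int s = 0; s < S; ++s)
            acc += wgl(i, s) * h0s[off + s] * std::exp(am1 * sgl(i, s));
          cumh = std::exp(lin) * acc;
          if (delta[i] == 1)
            ll += lw + std::log(shape) + (shape - 1.0) * std::log(Ti) +
              lin + am1 * Ti;
        } else {
          double acc = 0.0;
          double s1 = 0.0;
          for (int j = 0; j < J; ++j) {
            double s2 = (j < J - 1) ? knots[j] : Ti;
            if (s2 > Ti) s2 = Ti;
            if (s2 > s1) {
              double seg;
              if (std::fabs(am1) < 1e-12) seg = s2 - s1;
              else seg = (std::exp(am1 * s2) - std::exp(am1 * s1)) / am1;
              acc += std::exp(bl[j]) * seg;
            }
            s1 = s2;
            if (s1 >= Ti) break;
          }
          cumh = std::exp(lin) * acc;
          if (delta[i] == 1) ll += bl[jT] + lin + am1 * Ti;
        }
        if (!std::isfinite(cumh)) cumh = 1e300;  // overflow clip
        ll -= cumh;
      }
      // random-effects prior
      const double qf = b0 * (i11 * b0 + i12 * b1) +
        b1 * (i12 * b0 + i22 * b1);
      ll += -log2pi - 0.5 * ldetD - 0.5 * qf;
      ll += logw(i, q);
      node_ll[q] = ll;
      if (ll > best) best = ll;
    }
    if (!std::isfinite(best)) {
      out[i] = R_NegInf;
      continue;
    }
    double acc = 0.0;
    for (int q = 0; q < G; ++q) acc += std::exp(node_ll[q] - best);
    out[i] = best + std::log(acc);
  }
  return out;
}
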
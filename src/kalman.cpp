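#include <Rcpp.h>
using namespace Rcpp;

// Discrete two-state Kalman filter for magnitude estimation in log space.
//
// State X = (x, m): x is the current stimulus (drawn around the distribution
// mean m, variance v), m is the mean itself (random walk, increment variance
// q). Measurement z = x + noise, noise variance normalised to r = 1.
//
//   F = [[0, 1], [0, 1]],  H = [1, 0],  Q = diag(v, q)
//
// The prediction step collapses both states onto the previous mean estimate,
// so only the (2,2) entry of the posterior covariance enters the next
// prediction; the full 2x2 trace is still returned.
// [[Rcpp::export]]
List kalman_two_state_cpp(NumericVector z, double v, double q,
                          double m0, double p0) {
  const int n = z.size();
  NumericVector xh(n), mh(n), k1(n), k2(n), P11(n), P12(n), P22(n);
  double mprev = m0;
  double a22 = p0;  // posterior var of m from previous trial

  for (int i = 0; i < n; i++) {
    // predict: X_pred = F X_prev = (m_prev, m_prev)
    // P_pred = F P F' + Q; F P F' has all entries equal to a22
    const double b11 = a22 + v;
    const double b12 = a22;
    const double b22 = a22 + q;

    const double s = b11 + 1.0;            // innovation variance, r = 1
    const double g1 = b11 / s;             // gain on x
    const double g2 = b12 / s;             // gain on m
    const double innov = z[i] - mprev;

    xh[i] = mprev + g1 * innov;
    mh[i] = mprev + g2 * innov;
    k1[i] = g1;
    k2[i] = g2;

    // P_post = (I - K H) P_pred
    P11[i] = (1.0 - g1) * b11;
    P12[i] = (1.0 - g1) * b12;
    P22[i] = b22 - g2 * b12;

    mprev = mh[i];
    a22 = P22[i];
  }
  return List::create(_["x_hat"] = xh, _["m_hat"] = mh,
                      _["k1"] = k1, _["k2"] = k2,
                      _["p11"] = P11, _["p12"] = P12, _["p22"] = P22);
}
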
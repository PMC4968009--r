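// Exact state-space machinery for the aperiodic continuous-time movement
// models (OU position, integrated OU, OUF position-velocity) on irregular
// time grids: Gaussian transition matrices, Kalman-filter log-likelihoods
// conditioned on the first fix (stationary mean profiled where present),
// and exact recursive simulators driven by standard normals supplied from R
// so that all randomness stays under R's RNG.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 2x2 transition matrix Phi and innovation covariance Q over a step dt for
// the OUF process with rates l1 = 1/tau_pos, l2 = 1/tau_vel and stationary
// covariance diag(sxx, svv).  Near-equal rates use the confluent
// (critically damped) limit.
static void ouf_step(double dt, double l1, double l2, double sxx, double svv,
                     double phi[4], double q[3]) {
  double p00, p01, p10, p11;
  if (std::fabs(l1 - l2) > 1e-8 * (l1 + l2)) {
    double e1 = std::exp(-l1 * dt), e2 = std::exp(-l2 * dt);
    double d = l2 - l1;
    p00 = (l2 * e1 - l1 * e2) / d;
    p01 = (e1 - e2) / d;
    p10 = -l1 * l2 * (e1 - e2) / d;
    p11 = (l2 * e2 - l1 * e1) / d;
  } else {
    double l = 0.5 * (l1 + l2), e = std::exp(-l * dt);
    p00 = e * (1.0 + l * dt);
    p01 = e * dt;
    p10 = -e * l * l * dt;
    p11 = e * (1.0 - l * dt);
  }
  phi[0] = p00; phi[1] = p01; phi[2] = p10; phi[3] = p11;
  // Q = Sigma_inf - Phi Sigma_inf Phi' with Sigma_inf = diag(sxx, svv)
  q[0] = sxx - (p00 * p00 * sxx + p01 * p01 * svv);
  q[1] = -(p00 * p10 * sxx + p01 * p11 * svv);
  q[2] = svv - (p10 * p10 * sxx + p11 * p11 * svv);
}

// IOU transition over dt: x' = v, dv = -lv*v dt + noise, stationary
// velocity variance svv.
static void iou_step(double dt, double lv, double svv,
                     double phi[4], double q[3]) {
  double e = std::exp(-lv * dt);
  phi[0] = 1.0; phi[1] = (1.0 - e) / lv;
  phi[2] = 0.0; phi[3] = e;
  q[0] = (svv / (lv * lv)) * (2.0 * lv * dt - 3.0 + 4.0 * e - e * e);
  q[1] = (svv / lv) * (1.0 - e) * (1.0 - e);
  q[2] = svv * (1.0 - e * e);
}

// Generic 2-state Kalman log-likelihood with exact position observations,
// conditioned on the first record.  Y is N x K; the regression (ones)
// series profiles out a common stationary mean when profile_mean is true.
// Covariance recursion is data-independent so it is run once and shared
// across dimensions and the regression series.
static double kalman2_loglik(const NumericVector& t, const NumericMatrix& Y,
                             bool iou, double l1, double l2,
                             double sxx, double svv, bool profile_mean) {
  int n = t.size(), K = Y.ncol();
  if (n < 2) return 0.0;
  std::vector<double> S(n), k0(n), k1(n), phi00(n), phi01(n), phi10(n), phi11(n);
  // covariance pass
  double P00 = 0.0, P01 = 0.0, P11 = svv;  // after conditioning on first fix
  for (int j = 1; j < n; ++j) {
    double dt = t[j] - t[j - 1];
    double phi[4], q[3];
    if (iou) iou_step(dt, l2, svv, phi, q);
    else ouf_step(dt, l1, l2, sxx, svv, phi, q);
    phi00[j] = phi[0]; phi01[j] = phi[1]; phi10[j] = phi[2]; phi11[j] = phi[3];
    // predict
    double A00 = phi[0] * P00 + phi[1] * P01;
    double A01 = phi[0] * P01 + phi[1] * P11;
    double A10 = phi[2] * P00 + phi[3] * P01;
    double A11 = phi[2] * P01 + phi[3] * P11;
    double Pp00 = A00 * phi[0] + A01 * phi[1] + q[0];
    double Pp01 = A00 * phi[2] + A01 * phi[3] + q[1];
    double Pp11 = A10 * phi[2] + A11 * phi[3] + q[2];
    if (!(Pp00 > 0.0) || !std::isfinite(Pp00)) return R_NegInf;
    S[j] = Pp00;
    k0[j] = 1.0;             // gain for x-component (exact observation)
    k1[j] = Pp01 / Pp00;     // gain for v-component
    // update: P = Pp - K * [Pp00, Pp01]
    P00 = 0.0;
    P01 = 0.0;
    P11 = Pp11 - k1[j] * Pp01;
    if (P11 < 0.0) P11 = 0.0;
  }
  // mean pass on each data column and (optionally) the ones series
  // state after update: x = observed, v = filtered
  std::vector<double> nu1(n, 0.0);
  if (profile_mean) {
    double ax = 1.0, av = 0.0;
    for (int j = 1; j < n; ++j) {
      double px = phi00[j] * ax + phi01[j] * av;
      double pv = phi10[j] * ax + phi11[j] * av;
      nu1[j] = 1.0 - px;
      ax = px + k0[j] * nu1[j];   // = 1
      av = pv + k1[j] * nu1[j];
    }
  }
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    std::vector<double> nuy(n);
    double ax = Y(0, k), av = 0.0;
    for (int j = 1; j < n; ++j) {
      double px = phi00[j] * ax + phi01[j] * av;
      double pv = phi10[j] * ax + phi11[j] * av;
      nuy[j] = Y(j, k) - px;
      ax = px + k0[j] * nuy[j];   // = Y(j,k)
      av = pv + k1[j] * nuy[j];
    }
    double mu = 0.0;
    if (profile_mean) {
      double num = 0.0, den = 0.0;
      for (int j = 1; j < n; ++j) {
        num += nu1[j] * nuy[j] / S[j];
        den += nu1[j] * nu1[j] / S[j];
      }
      if (den > 1e-300) mu = num / den;
    }
    for (int j = 1; j < n; ++j) {
      double r = nuy[j] - mu * nu1[j];
      ll += -0.5 * (std::log(2.0 * M_PI * S[j]) + r * r / S[j]);
    }
  }
  return std::isfinite(ll) ? ll : R_NegInf;
}

// [[Rcpp::export]]
double ll_ou_cpp(NumericVector t, NumericMatrix Y, double sigma, double tau) {
  int n = t.size(), K = Y.ncol();
  if (!(sigma > 0.0) || !(tau > 0.0)) return R_NegInf;
  if (n < 2) return 0.0;
  // AR(1) innovations conditioned on the first record; mean profiled
  double ll = 0.0;
  std::vector<double> e(n), S(n);
  for (int j = 1; j < n; ++j) {
    e[j] = std::exp(-(t[j] - t[j - 1]) / tau);
    S[j] = sigma * (1.0 - e[j] * e[j]);
    if (!(S[j] > 0.0)) return R_NegInf;
  }
  for (int k = 0; k < K; ++k) {
    double num = 0.0, den = 0.0;
    for (int j = 1; j < n; ++j) {
      double nuy = Y(j, k) - e[j] * Y(j - 1, k);
      double nu1 = 1.0 - e[j];
      num += nu1 * nuy / S[j];
      den += nu1 * nu1 / S[j];
    }
    double mu = den > 1e-300 ? num / den : 0.0;
    for (int j = 1; j < n; ++j) {
      double r = (Y(j, k) - e[j] * Y(j - 1, k)) - mu * (1.0 - e[j]);
      ll += -0.5 * (std::log(2.0 * M_PI * S[j]) + r * r / S[j]);
    }
  }
  return std::isfinite(ll) ? ll : R_NegInf;
}

// [[Rcpp::export]]
double ll_iou_cpp(NumericVector t, NumericMatrix Y, double sigma, double tau_vel) {
  if (!(sigma > 0.0) || !(tau_vel > 0.0)) return R_NegInf;
  double svv = sigma / (2.0 * tau_vel);
  return kalman2_loglik(t, Y, true, 0.0, 1.0 / tau_vel, 0.0, svv, false);
}

// [[Rcpp::export]]
double ll_ouf_cpp(NumericVector t, NumericMatrix Y, double sigma,
                  double tau_pos, double tau_vel) {
  if (!(sigma > 0.0) || !(tau_pos > 0.0) || !(tau_vel > 0.0)) return R_NegInf;
  if (tau_vel >= tau_pos) return R_NegInf;
  double svv = sigma / (tau_pos * tau_vel);
  return kalman2_loglik(t, Y, false, 1.0 / tau_pos, 1.0 / tau_vel,
                        sigma, svv, true);
}

// [[Rcpp::export]]
NumericMatrix sim_ou_cpp(NumericVector t, double sigma, double tau,
                         NumericMatrix Z) {
  int n = t.size(), K = Z.ncol();
  NumericMatrix X(n, K);
  double sd0 = std::sqrt(sigma);
  for (int k = 0; k < K; ++k) {
    X(0, k) = sd0 * Z(0, k);
    for (int j = 1; j < n; ++j) {
      double e = std::exp(-(t[j] - t[j - 1]) / tau);
      X(j, k) = e * X(j - 1, k) + std::sqrt(sigma * (1.0 - e * e)) * Z(j, k);
    }
  }
  return X;
}

// Exact 2-state simulation shared by IOU and OUF; Zx, Zv are N x K standard
// normals.  IOU starts at the origin with stationary velocity; OUF starts in
// its stationary distribution.
static NumericMatrix sim2(const NumericVector& t, bool iou, double l1, double l2,
                          double sxx, double svv,
                          const NumericMatrix& Zx, const NumericMatrix& Zv) {
  int n = t.size(), K = Zx.ncol();
  NumericMatrix X(n, K);
  for (int k = 0; k < K; ++k) {
    double x = iou ? 0.0 : std::sqrt(sxx) * Zx(0, k);
    double v = std::sqrt(svv) * Zv(0, k);
    X(0, k) = x;
    for (int j = 1; j < n; ++j) {
      double dt = t[j] - t[j - 1];
      double phi[4], q[3];
      if (iou) iou_step(dt, l2, svv, phi, q);
      else ouf_step(dt, l1, l2, sxx, svv, phi, q);
      // Cholesky of 2x2 q
      double L00 = std::sqrt(std::max(q[0], 0.0));
      double L10 = L00 > 0.0 ? q[1] / L00 : 0.0;
      double d22 = q[2] - L10 * L10;
      double L11 = std::sqrt(std::max(d22, 0.0));
      double nx = phi[0] * x + phi[1] * v + L00 * Zx(j, k);
      double nv = phi[2] * x + phi[3] * v + L10 * Zx(j, k) + L11 * Zv(j, k);
      x = nx; v = nv;
      X(j, k) = x;
    }
  }
  return X;
}

// [[Rcpp::export]]
NumericMatrix sim_iou_cpp(NumericVector t, double sigma, double tau_vel,
                          NumericMatrix Zx, NumericMatrix Zv) {
  double svv = sigma / (2.0 * tau_vel);
  return sim2(t, true, 0.0, 1.0 / tau_vel, 0.0, svv, Zx, Zv);
}

// [[Rcpp::export]]
NumericMatrix sim_ouf_cpp(NumericVector t, double sigma, double tau_pos,
                          double tau_vel, NumericMatrix Zx, NumericMatrix Zv) {
  double svv = sigma / (tau_pos * tau_vel);
  return sim2(t, false, 1.0 / tau_pos, 1.0 / tau_vel, sigma, svv, Zx, Zv);
}
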
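#include <Rcpp.h>
using namespace Rcpp;

// Free-run simulation of a discrete-time linear state-space model
//   X(n+1) = A X(n) + B u(n),  y(n+1) = C X(n+1) + D u(n+1)
// from X(0) = x0, with the schedule holding u(1..N) aligned with the
// observed strides and u(0) taken as the schedule's first entry.
// State dimension k is 1 or 2; kept generic for safety.
// [[Rcpp::export]]
NumericVector sim_lds(NumericMatrix A, NumericVector B, NumericVector C,
                      double D, NumericVector x0, NumericVector u) {
  const int k = A.nrow();
  if (A.ncol() != k || B.size() != k || C.size() != k || x0.size() != k)
    stop("inconsistent state-space dimensions");
  const int N = u.size();
  if (N < 1) stop("empty input schedule");
  NumericVector y(N);
  std::vector<double> x(x0.begin(), x0.end()), xn(k);
  for (int n = 0; n < N; ++n) {
    // u(n-1), with u(0) aliased to the first schedule entry
    const double uprev = (n == 0) ? u[0] : u[n - 1];
    for (int i = 0; i < k; ++i) {
      double s = B[i] * uprev;
      for (int j = 0; j < k; ++j) s += A(i, j) * x[j];
      xn[i] = s;
    }
    double yo = D * u[n];
    for (int i = 0; i < k; ++i) {
      x[i] = xn[i];
      yo += C[i] * x[i];
    }
    y[n] = yo;
  }
  return y;
}

// Residual sum of squares of the free-run simulation against observations,
// skipping the .Call/vector overhead of sim_lds inside optimizers.
// [[Rcpp::export]]
double sse_lds(NumericMatrix A, NumericVector B, NumericVector C,
               double D, NumericVector x0, NumericVector u,
               NumericVector yobs) {
  const int k = A.nrow();
  const int N = u.size();
  if (yobs.size() != N) stop("schedule and observations differ in length");
  double sse = 0.0;
  std::vector<double> x(x0.begin(), x0.end()), xn(k);
  for (int n = 0; n < N; ++n) {
    const double uprev = (n == 0) ? u[0] : u[n - 1];
    for (int i = 0; i < k; ++i) {
      double s = B[i] * uprev;
      for (int j = 0; j < k; ++j) s += A(i, j) * x[j];
      xn[i] = s;
    }
    double yo = D * u[n];
    for (int i = 0; i < k; ++i) {
      x[i] = xn[i];
      yo += C[i] * x[i];
    }
    const double r = yobs[n] - yo;
    sse += r * r;
  }
  return sse;
}

static double spectral_radius2(double a11, double a12, double a21, double a22) {
  const double tr = a11 + a22, dt = a11 * a22 - a12 * a21;
  const double disc = tr * tr - 4.0 * dt;
  if (disc >= 0.0) {
    const double s = std::sqrt(disc);
    return std::max(std::fabs(tr + s), std::fabs(tr - s)) / 2.0;
  }
  return std::sqrt(dt);
}

// Penalized free-run least-squares objective for one model family.
// family_id: 1 single_state, 2 udl, 3 fast_slow, 4 modified_udl, 5 two_state.
// Maps the native parameter vector to canonical (A, B, C, D), simulates from
// a zero state, and adds the quadratic penalty for non-box constraints with
// interior margin eps and weight w (see fit_options()).
// [[Rcpp::export]]
double fit_objective(int family_id, NumericVector theta, NumericVector u,
                     NumericVector yobs, double eps, double w) {
  double A[2][2] = {{0, 0}, {0, 0}}, B[2] = {0, 0}, C[2] = {0, 0}, D = 0;
  int k = 2;
  double g = 0.0;
  switch (family_id) {
  case 1:  // single_state: canonical (a', b', c, d); |a'|<=1 is box-handled
    k = 1; A[0][0] = theta[0]; B[0] = theta[1]; C[0] = theta[2]; D = theta[3];
    break;
  case 2:  // udl (au, bu, du): A = au+bu, B = bu*du, C = 1, D = du
    k = 1; A[0][0] = theta[0] + theta[1]; B[0] = theta[1] * theta[2];
    C[0] = 1.0; D = theta[2];
    g = std::max(0.0, std::fabs(theta[0] + theta[1]) - (1.0 - eps));
    break;
  case 3:  // fast_slow (af, bf, as, bs, d)
    A[0][0] = theta[0]; A[1][1] = theta[2];
    B[0] = theta[4] * theta[1]; B[1] = theta[4] * theta[3];
    C[0] = 1.0; C[1] = 1.0; D = theta[4];
    g = std::max(0.0, theta[0] - theta[2] + eps) +  // as >= af + eps
        std::max(0.0, theta[3] - theta[1] + eps) +  // bf >= bs + eps
        std::max(0.0, eps - theta[0]);              // af >= eps
    break;
  case 4:  // modified_udl (amu, bmu, cmu, dmu)
    A[0][0] = theta[2]; A[0][1] = 1.0 - theta[2];
    A[1][0] = 1.0 - theta[0] - theta[1]; A[1][1] = theta[0] + theta[1];
    B[0] = theta[3] * (1.0 - theta[2]); B[1] = theta[3] * theta[1];
    C[0] = 0.0; C[1] = 1.0; D = theta[3];
    g = std::max(0.0, std::fabs(theta[0] + theta[1] + theta[2] - 1.0) -
                          (1.0 - eps));
    break;
  case 5:  // two_state (a11, a12, a21, a22, b1, b2, c1, c2, d)
    A[0][0] = theta[0]; A[0][1] = theta[1]; A[1][0] = theta[2];
    A[1][1] = theta[3]; B[0] = theta[4]; B[1] = theta[5];
    C[0] = theta[6]; C[1] = theta[7]; D = theta[8];
    g = std::max(0.0, spectral_radius2(theta[0], theta[1], theta[2],
                                       theta[3]) - 1.0);
    break;
  default:
    stop("unknown family id");
  }
  const int N = u.size();
  if (yobs.size() != N) stop("schedule and observations differ in length");
  double x0 = 0.0, x1 = 0.0, sse = 0.0;
  for (int n = 0; n < N; ++n) {
    const double uprev = (n == 0) ? u[0] : u[n - 1];
    const double n0 = A[0][0] * x0 + A[0][1] * x1 + B[0] * uprev;
    const double n1 = A[1][0] * x0 + A[1][1] * x1 + B[1] * uprev;
    x0 = n0; x1 = n1;
    const double r = yobs[n] - (C[0] * x0 + C[1] * x1 + D * u[n]);
    sse += r * r;
    if (!std::isfinite(sse)) return 1e30;
  }
  (void)k;
  return sse + w * g * g;
}
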
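// Adaptive Dormand-Prince 5(4) integration of the growth systems.
//
// Two right-hand sides are hard-coded: the coupled two-tumor system (Gompertz,
// logistic or exponential; shared or individual capacities) and the augmented
// ODE reduction of the size-structured metastasis model. Both are integrated
// with the same embedded RK pair; output times are hit exactly by clamping
// steps to the requested grid.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

namespace {

const double VOL_FLOOR = 1e-12;  // floor inside logs; a tumor at exactly 0 stays 0

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// difference between 5th- and embedded 4th-order weights
const double d1 = b1 - 5179.0 / 57600, d3 = b3 - 7571.0 / 16695,
             d4 = b4 - 393.0 / 640, d5 = b5 + 92097.0 / 339200,
             d6 = b6 - 187.0 / 2100, d7 = -1.0 / 40;

typedef std::function<void(double, const double*, double*)> RhsFun;

// Integrate y' = f(t, y) from t0 to t1 (single leg, no output in between).
// nsteps accumulates across legs; exceeding max_steps aborts the simulation
// (calibration treats that as an infinite-objective penalty).
void dopri5_leg(const RhsFun& f, std::vector<double>& y, double t0, double t1,
                double rtol, double atol, double& hinit, long& nsteps,
                long max_steps) {
  const int n = (int)y.size();
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y5(n);
  double t = t0;
  double h = (hinit > 0) ? hinit : (t1 - t0) / 100.0;
  if (t1 <= t0) stop("time grid must be strictly increasing");
  h = std::min(h, t1 - t0);
  f(t, y.data(), k1.data());

  while (t < t1) {
    if (++nsteps > max_steps) stop("solver exceeded the step budget (t = %f)", t);
    bool last = false;
    if (t + h >= t1) { h = t1 - t; last = true; }

    for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    f(t + c2 * h, ytmp.data(), k2.data());
    for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    f(t + c3 * h, ytmp.data(), k3.data());
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    f(t + c4 * h, ytmp.data(), k4.data());
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    f(t + c5 * h, ytmp.data(), k5.data());
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    f(t + h, ytmp.data(), k6.data());
    for (int j = 0; j < n; ++j)
      y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                          b6 * k6[j]);
    f(t + h, y5.data(), k7.data());

    double err = 0.0;
    for (int j = 0; j < n; ++j) {
      double de = h * (d1 * k1[j] + d3 * k3[j] + d4 * k4[j] + d5 * k5[j] +
                       d6 * k6[j] + d7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
      double e = de / sc;
      err += e * e;
    }
    err = std::sqrt(err / n);

    if (err <= 1.0 || h <= 1e-12 * std::max(1.0, std::fabs(t))) {
      t += h;
      y = y5;
      k1 = k7;  // first-same-as-last
      for (int j = 0; j < n; ++j)
        if (!R_finite(y[j])) stop("solver produced a non-finite state at t = %f", t);
      if (last && t >= t1) { hinit = h; }
    } else {
      last = false;
    }
    double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12) h = 1e-12;
    if (!last) hinit = h;
  }
}

double safe_log_ratio(double K, double s) {
  return std::log(K / std::max(s, VOL_FLOOR));
}

}  // namespace

// law: 0 = gompertz, 1 = logistic, 2 = exponential
// shared: true -> one capacity K1 for the summed burden; false -> K1, K2 individual
// [[Rcpp::export]]
NumericMatrix cpp_simulate_two_tumor(int law, double r1, double r2, double K1,
                                     double K2, bool shared, double T10,
                                     double T20, NumericVector times,
                                     double rtol, double atol,
                                     double max_steps = 2e6) {
  RhsFun f = [&](double t, const double* y, double* dy) {
    (void)t;
    double T1 = y[0], T2 = y[1];
    double g1, g2;
    if (law == 2) {
      g1 = r1; g2 = r2;
    } else if (shared) {
      double S = std::max(T1, 0.0) + std::max(T2, 0.0);
      double m = (law == 0) ? safe_log_ratio(K1, S) : (1.0 - S / K1);
      g1 = r1 * m; g2 = r2 * m;
    } else {
      g1 = r1 * ((law == 0) ? safe_log_ratio(K1, T1) : (1.0 - T1 / K1));
      g2 = r2 * ((law == 0) ? safe_log_ratio(K2, T2) : (1.0 - T2 / K2));
    }
    dy[0] = (T1 > 0) ? g1 * T1 : 0.0;
    dy[1] = (T2 > 0) ? g2 * T2 : 0.0;
  };
  const int nt = times.size();
  NumericMatrix out(nt, 2);
  std::vector<double> y = {T10, T20};
  out(0, 0) = T10; out(0, 1) = T20;
  double h = -1;
  long nsteps = 0;
  for (int i = 1; i < nt; ++i) {
    dopri5_leg(f, y, times[i - 1], times[i], rtol, atol, h, nsteps,
               (long)max_steps);
    out(i, 0) = y[0]; out(i, 1) = y[1];
  }
  colnames(out) = CharacterVector::create("T1", "T2");
  return out;
}

// Augmented ODE reduction of the metastasis model. All sizes in cells.
//
// Instead of storing the density rho(x,t), the model is reduced exactly along
// characteristics: a metastasis born at time s has size exp(am (G(t) - G(s)))
// with G = int ln(K/theta) dt. The burden M = int x rho dx and the seeding
// moment Q = int x^chi rho dx then satisfy plain ODEs,
//   dM/dt = am M ln(K/theta) + B,   dQ/dt = chi am Q ln(K/theta) + B,
// (every newborn enters at size 1, hence the +B), which is the numerically
// stable form of the exp(am G)-weighted accumulators: no large exponential is
// ever formed.
//
// States: x (primary, cells), G, M, Q, N. B is algebraic:
//   B = mu max(0, 1 - theta/K) (x_seed^chi + Q),  theta = x + M.
//
// surgery_mode: 0 none; 1 resect (x -> 0, capacity freed); 2 arrest (growth
// and seeding stop, the primary's mass stays in theta as a capacity footprint).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_metastatic(double aPT, double am, double K,
                                      double mu, double chi, double x0,
                                      NumericVector times, double surgery_time,
                                      int surgery_mode, double rtol,
                                      double atol, double max_steps = 2e6) {
  const int nt = times.size();
  const bool has_surgery = R_finite(surgery_time) && surgery_mode > 0 &&
                           surgery_time > times[0] && surgery_time <= times[nt - 1];
  bool primary_on = true;  // growth + seeding active

  RhsFun f = [&](double t, const double* y, double* dy) {
    (void)t;
    double x = y[0], M = y[2], Q = y[3];
    double theta = x + M;
    double lg = safe_log_ratio(K, theta);
    double seed = (primary_on && x > 0) ? std::pow(x, chi) : 0.0;
    double B = mu * std::max(0.0, 1.0 - theta / K) * (seed + std::max(Q, 0.0));
    dy[0] = (primary_on && x > 0) ? aPT * x * lg : 0.0;
    dy[1] = lg;
    dy[2] = am * M * lg + B;
    dy[3] = chi * am * Q * lg + B;
    dy[4] = B;
  };

  NumericMatrix out(nt, 7);
  colnames(out) = CharacterVector::create("x_PT", "theta", "B", "G", "N", "M",
                                          "Q");
  std::vector<double> y = {x0, 0.0, 0.0, 0.0, 0.0};
  double h = -1;
  long nsteps = 0;
  const long msteps = (long)max_steps;
  bool event_done = !has_surgery;

  auto apply_event = [&]() {
    if (surgery_mode == 1) y[0] = 0.0;  // resect: mass leaves the burden
    else primary_on = false;            // arrest: mass stays, growth/seeding stop
    if (surgery_mode == 1) primary_on = true;  // a resected x=0 seeds nothing anyway
    event_done = true;
    h = -1;  // restart step-size control after the discontinuity
  };

  auto emit = [&](int i) {
    double x = y[0], G = y[1], M = y[2], Q = y[3], N = y[4];
    double theta = x + M;
    double seed = (primary_on && x > 0) ? std::pow(x, chi) : 0.0;
    double B = mu * std::max(0.0, 1.0 - theta / K) * (seed + std::max(Q, 0.0));
    out(i, 0) = x; out(i, 1) = theta; out(i, 2) = B; out(i, 3) = G;
    out(i, 4) = N; out(i, 5) = M; out(i, 6) = Q;
  };

  emit(0);
  for (int i = 1; i < nt; ++i) {
    double t0 = times[i - 1], t1 = times[i];
    if (!event_done && surgery_time > t0 && surgery_time <= t1) {
      if (surgery_time > t0)
        dopri5_leg(f, y, t0, surgery_time, rtol, atol, h, nsteps, msteps);
      apply_event();
      if (surgery_time < t1)
        dopri5_leg(f, y, surgery_time, t1, rtol, atol, h, nsteps, msteps);
    } else {
      dopri5_leg(f, y, t0, t1, rtol, atol, h, nsteps, msteps);
    }
    emit(i);
  }
  return out;
}
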
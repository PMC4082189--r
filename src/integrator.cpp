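#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Coupled bilinear-neural / balloon-hemodynamic state integrator.
//
// State layout (length 5n): z[0..n), s, f, v, q. Inputs are held constant
// over each integration step (zero-order hold at resolution dt).
//
// Hemodynamic parameter matrix H is 7 x n with rows
//   tau, alpha_grubb, E0, V0, tau_s, tau_f, epsilon.
//
// BOLD observation (percent signal change):
//   y = 100 * V0 * (k1 (1-q) + k2 (1-q/v) + k3 (1-v)),
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.

static inline void dcm_deriv(int n, int m,
                             const double* state, const double* u,
                             const double* A, double alpha_decay,
                             const double* B, const double* C,
                             const double* H, double* d) {
  const double* z = state;
  const double* s = state + n;
  const double* f = state + 2 * n;
  const double* v = state + 3 * n;
  const double* q = state + 4 * n;

  // dz = (alpha * A + sum_j u_j B_j) z + C u
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      double coef = alpha_decay * A[i + n * k];
      for (int j = 0; j < m; ++j)
        coef += u[j] * B[i + n * k + n * n * j];
      acc += coef * z[k];
    }
    for (int j = 0; j < m; ++j)
      acc += C[i + n * j] * u[j];
    d[i] = acc;
  }

  for (int i = 0; i < n; ++i) {
    const double tau   = H[0 + 7 * i];
    const double alph  = H[1 + 7 * i];
    const double E0    = H[2 + 7 * i];
    const double tau_s = H[4 + 7 * i];
    const double tau_f = H[5 + 7 * i];
    const double eps   = H[6 + 7 * i];

    // v^(1/alpha) and (1-E0)^(1/f) via exp/log (cheaper than pow)
    const double fv = std::exp(std::log(v[i]) / alph); // outflow f_out(v)
    const double Ef = 1.0 - std::exp(std::log(1.0 - E0) / f[i]);

    d[n + i]     = eps * z[i] - s[i] / tau_s - (f[i] - 1.0) / tau_f;
    d[2 * n + i] = s[i];
    d[3 * n + i] = (f[i] - fv) / tau;
    d[4 * n + i] = (f[i] * Ef / E0 - fv * q[i] / v[i]) / tau;
  }
}

// [[Rcpp::export]]
List integrate_dcm_cpp(NumericMatrix A, double alpha_decay,
                       NumericVector Barr, NumericMatrix C,
                       NumericMatrix U, double dt,
                       int stride, int n_samples,
                       NumericMatrix H, bool keep_neural,
                       bool use_euler) {
  const int n = A.nrow();
  const int m = C.ncol();
  if (U.ncol() != m) stop("input matrix has %d columns; expected %d", U.ncol(), m);
  if (H.nrow() != 7 || H.ncol() != n) stop("hemodynamic parameter matrix must be 7 x n");
  const int n_steps = (n_samples - 1) * stride;
  if (U.nrow() < n_steps) stop("input series too short: %d rows, need %d", U.nrow(), n_steps);

  const double* Ap = A.begin();
  const double* Bp = Barr.begin();
  const double* Cp = C.begin();
  const double* Hp = H.begin();

  const int ns = 5 * n;
  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  for (int i = 0; i < n; ++i) {            // resting fixed point
    x[2 * n + i] = 1.0;
    x[3 * n + i] = 1.0;
    x[4 * n + i] = 1.0;
  }

  NumericMatrix bold(n_samples, n);
  NumericMatrix neural(keep_neural ? n_samples : 1, keep_neural ? n : 1);
  std::vector<double> u(m);

  int sample = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % stride == 0) {
      for (int i = 0; i < n; ++i) {
        const double E0 = Hp[2 + 7 * i], V0 = Hp[3 + 7 * i];
        const double k1b = 7.0 * E0, k2b = 2.0, k3b = 2.0 * E0 - 0.2;
        const double v = x[3 * n + i], q = x[4 * n + i];
        bold(sample, i) = 100.0 * V0 *
          (k1b * (1.0 - q) + k2b * (1.0 - q / v) + k3b * (1.0 - v));
        if (keep_neural) neural(sample, i) = x[i];
      }
      ++sample;
      if (sample == n_samples) break;
    }
    for (int j = 0; j < m; ++j) u[j] = U(step, j);

    if (use_euler) {
      dcm_deriv(n, m, x.data(), u.data(), Ap, alpha_decay, Bp, Cp, Hp, k1.data());
      for (int i = 0; i < ns; ++i) x[i] += dt * k1[i];
    } else {
      dcm_deriv(n, m, x.data(), u.data(), Ap, alpha_decay, Bp, Cp, Hp, k1.data());
      for (int i = 0; i < ns; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
      dcm_deriv(n, m, tmp.data(), u.data(), Ap, alpha_decay, Bp, Cp, Hp, k2.data());
      for (int i = 0; i < ns; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
      dcm_deriv(n, m, tmp.data(), u.data(), Ap, alpha_decay, Bp, Cp, Hp, k3.data());
      for (int i = 0; i < ns; ++i) tmp[i] = x[i] + dt * k3[i];
      dcm_deriv(n, m, tmp.data(), u.data(), Ap, alpha_decay, Bp, Cp, Hp, k4.data());
      for (int i = 0; i < ns; ++i)
        x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }

    bool bad = false;
    for (int i = 0; i < ns; ++i)
      if (!std::isfinite(x[i])) { bad = true; break; }
    for (int i = 0; i < n && !bad; ++i)
      if (x[2 * n + i] <= 0.0 || x[3 * n + i] <= 0.0 || x[4 * n + i] <= 0.0)
        bad = true;
    if (bad)
      stop("integration diverged (non-finite or non-positive hemodynamic state) at step %d (t = %.3f s)",
           step + 1, (step + 1) * dt);
  }

  List out = List::create(_["bold"] = bold);
  if (keep_neural) out["neural"] = neural;
  return out;
}
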
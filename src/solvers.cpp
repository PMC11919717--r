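#include <Rcpp.h>
using namespace Rcpp;

// Time-domain solvers for an inertialess trapped bead in a linear
// viscoelastic medium.  Force balance at every instant:
//   F_material(x; history) = k * (xl(t) - x(t)),  x(0) = 0, zero pre-history.
// Units: pN, um, s (so Pa == pN/um^2); xl is the equivalent single-trap
// trajectory sampled on a uniform grid t_n = n * dt.

// Gruenwald-Letnikov solver for stress-additive families
// (springpot / fractional Kelvin-Voigt):
//   6 pi a * sum_j C_j D_t^{alpha_j} x = k (xl - x)
// D_t^a x(t_n) ~ dt^-a * sum_m w_m^(a) x_{n-m}, w_0 = 1,
// w_m = w_{m-1} * (1 - (a+1)/m).  The per-term kernels are combined into a
// single memory kernel K so each step is one dot product.  `memory` > 0
// truncates the history window (short-memory principle); 0 = full memory.
// [[Rcpp::export(name = ".gl_solve")]]
NumericVector gl_solve(NumericVector xl, double dt, double k,
                       double six_pi_a, NumericVector C,
                       NumericVector alpha, int memory = 0) {
  const int n = xl.size();
  const int nj = C.size();
  const int L = (memory > 0 && memory < n) ? memory : n;
  // combined kernel K[m] = sum_j six_pi_a * C_j dt^-alpha_j * w_m^(alpha_j)
  std::vector<double> K(n, 0.0);
  for (int j = 0; j < nj; ++j) {
    const double a = alpha[j];
    const double pref = six_pi_a * C[j] * std::pow(dt, -a);
    double w = 1.0;
    K[0] += pref;
    for (int m = 1; m < n; ++m) {
      w *= 1.0 - (a + 1.0) / m;
      if (m < L) K[m] += pref * w; else break;
    }
  }
  NumericVector x(n);
  x[0] = k * xl[0] / (k + K[0]);
  const double* Kp = K.data();
  const double* xp = REAL(x);
  for (int nstep = 1; nstep < n; ++nstep) {
    const int mmax = std::min(nstep, L - 1);
    // dot product with 4 accumulators to break the dependency chain
    double h0 = 0.0, h1 = 0.0, h2 = 0.0, h3 = 0.0;
    int m = 1;
    for (; m + 3 <= mmax; m += 4) {
      h0 += Kp[m] * xp[nstep - m];
      h1 += Kp[m + 1] * xp[nstep - m - 1];
      h2 += Kp[m + 2] * xp[nstep - m - 2];
      h3 += Kp[m + 3] * xp[nstep - m - 3];
    }
    for (; m <= mmax; ++m) h0 += Kp[m] * xp[nstep - m];
    x[nstep] = (k * xl[nstep] - (h0 + h1 + h2 + h3)) / (k + K[0]);
  }
  return x;
}

// Hereditary creep-integral (Volterra) solver for any family with a creep
// compliance J(t):  x(t) = (1/6 pi a) int_0^t J(t - s) dF(s),
// F = k (xl - x).  `kernel` holds J((m - 1/2) dt) / (6 pi a) at segment
// midpoints (bead compliance, um/pN), length >= length(xl).
// [[Rcpp::export(name = ".volterra_solve")]]
NumericVector volterra_solve(NumericVector xl, double k,
                             NumericVector kernel) {
  const int n = xl.size();
  if (kernel.size() < n) stop("volterra kernel shorter than trajectory");
  NumericVector x(n), F(n);
  const double c0 = kernel[0];
  x[0] = c0 * k * xl[0] / (1.0 + c0 * k);
  F[0] = k * (xl[0] - x[0]);
  std::vector<double> dF(n, 0.0);
  const double* kp = kernel.begin();
  for (int nstep = 1; nstep < n; ++nstep) {
    double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
    int m = 1;
    for (; m + 3 < nstep; m += 4) {
      s0 += kp[nstep - m] * dF[m];
      s1 += kp[nstep - m - 1] * dF[m + 1];
      s2 += kp[nstep - m - 2] * dF[m + 2];
      s3 += kp[nstep - m - 3] * dF[m + 3];
    }
    for (; m < nstep; ++m) s0 += kp[nstep - m] * dF[m];
    double s = s0 + s1 + s2 + s3;
    // implicit step: x_n = s + c0 * (F_n - F_{n-1}), F_n = k (xl_n - x_n)
    x[nstep] = (s + c0 * (k * xl[nstep] - F[nstep - 1])) / (1.0 + c0 * k);
    F[nstep] = k * (xl[nstep] - x[nstep]);
    dF[nstep] = F[nstep] - F[nstep - 1];
  }
  return x;
}

// O(N) Crank-Nicolson stepper for a Newtonian fluid:
//   6 pi a eta dx/dt = k (xl - x)
// [[Rcpp::export(name = ".newtonian_solve")]]
NumericVector newtonian_solve(NumericVector xl, double dt, double k,
                              double six_pi_a, double eta) {
  const int n = xl.size();
  const double c = six_pi_a * eta / dt;
  NumericVector x(n);
  x[0] = 0.0;  // bead at rest at t = 0 (xl[0] = 0 for the trapezoid drive)
  for (int i = 1; i < n; ++i) {
    x[i] = (c * x[i - 1] + 0.5 * k * (xl[i] + xl[i - 1]) -
            0.5 * k * x[i - 1]) / (c + 0.5 * k);
  }
  return x;
}

// O(N) Crank-Nicolson stepper for a Maxwell liquid (spring E, dashpot eta
// in series).  Material force F = k (xl - x) obeys
//   F + tau dF/dt = 6 pi a eta dx/dt,  tau = eta / E, giving
//   (6 pi a E + k) dx/dt = k dxl/dt + (k / tau)(xl - x).
// [[Rcpp::export(name = ".maxwell_solve")]]
NumericVector maxwell_solve(NumericVector xl, double dt, double k,
                            double six_pi_a, double eta, double E) {
  const int n = xl.size();
  const double tau = eta / E;
  const double A = (six_pi_a * E + k) / dt;
  const double B = k / tau;
  NumericVector x(n);
  x[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    const double rhs = A * x[i - 1] + k * (xl[i] - xl[i - 1]) / dt +
      0.5 * B * (xl[i] + xl[i - 1] - x[i - 1]);
    x[i] = rhs / (A + 0.5 * B);
  }
  return x;
}
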
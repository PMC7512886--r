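// Fixed-step RK4 core for the forced love model
//
//   dR/dt = a R + b J (1 - |J|) + y(t) [if forcing targets Romeo]
//   dJ/dt = c R (1 - |R|) + d J + y(t) [if forcing targets Juliet]
//   y(t)  = A sin(omega * pi * t) + B
//
// target codes: 0 = romeo, 1 = juliet, 2 = both.
// Fixed-step RK4 keeps strobe times exactly on the grid and makes runs
// bit-reproducible; the compiled loop keeps long sweeps cheap.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double forcing(double t, double A, double B, double omega) {
  return A * std::sin(omega * M_PI * t) + B;
}

static inline void deriv(double t, double R, double J,
                         double a, double b, double c, double d,
                         double A, double B, double omega, int target,
                         double &dR, double &dJ) {
  double y = forcing(t, A, B, omega);
  dR = a * R + b * J * (1.0 - std::fabs(J));
  dJ = c * R * (1.0 - std::fabs(R)) + d * J;
  if (target == 0 || target == 2) dR += y;
  if (target == 1 || target == 2) dJ += y;
}

// One RK4 step of the base system.
static inline void rk4_step(double t, double dt, double &R, double &J,
                            double a, double b, double c, double d,
                            double A, double B, double omega, int target) {
  double k1R, k1J, k2R, k2J, k3R, k3J, k4R, k4J;
  deriv(t, R, J, a, b, c, d, A, B, omega, target, k1R, k1J);
  deriv(t + 0.5 * dt, R + 0.5 * dt * k1R, J + 0.5 * dt * k1J,
        a, b, c, d, A, B, omega, target, k2R, k2J);
  deriv(t + 0.5 * dt, R + 0.5 * dt * k2R, J + 0.5 * dt * k2J,
        a, b, c, d, A, B, omega, target, k3R, k3J);
  deriv(t + dt, R + dt * k3R, J + dt * k3J,
        a, b, c, d, A, B, omega, target, k4R, k4J);
  R += dt * (k1R + 2.0 * k2R + 2.0 * k3R + k4R) / 6.0;
  J += dt * (k1J + 2.0 * k2J + 2.0 * k3J + k4J) / 6.0;
}

// Augmented derivative: base state plus a tangent vector propagated by the
// state Jacobian [[a, b(1-2|J|)], [c(1-2|R|), d]] (forcing is additive, so
// it does not enter the tangent dynamics).
static inline void deriv_aug(double t, const double *x,
                             double a, double b, double c, double d,
                             double A, double B, double omega, int target,
                             double *dx) {
  deriv(t, x[0], x[1], a, b, c, d, A, B, omega, target, dx[0], dx[1]);
  double j12 = b * (1.0 - 2.0 * std::fabs(x[1]));
  double j21 = c * (1.0 - 2.0 * std::fabs(x[0]));
  dx[2] = a * x[2] + j12 * x[3];
  dx[3] = j21 * x[2] + d * x[3];
}

static inline void rk4_step_aug(double t, double dt, double *x,
                                double a, double b, double c, double d,
                                double A, double B, double omega, int target) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  deriv_aug(t, x, a, b, c, d, A, B, omega, target, k1);
  for (int i = 0; i < 4; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  deriv_aug(t + 0.5 * dt, tmp, a, b, c, d, A, B, omega, target, k2);
  for (int i = 0; i < 4; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  deriv_aug(t + 0.5 * dt, tmp, a, b, c, d, A, B, omega, target, k3);
  for (int i = 0; i < 4; ++i) tmp[i] = x[i] + dt * k3[i];
  deriv_aug(t + dt, tmp, a, b, c, d, A, B, omega, target, k4);
  for (int i = 0; i < 4; ++i)
    x[i] += dt * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
}

// [[Rcpp::export(name = ".rk4_integrate_cpp")]]
List rk4_integrate_cpp(double a, double b, double c, double d,
                       double A, double B, double omega, int target,
                       double R0, double J0, double t0, double dt,
                       double n_transient_steps, double n_record_steps,
                       double guard) {
  long nt = (long) n_transient_steps;
  long nr = (long) n_record_steps;
  double R = R0, J = J0;
  // transient: not recorded
  for (long i = 0; i < nt; ++i) {
    double t = t0 + (double) i * dt;
    rk4_step(t, dt, R, J, a, b, c, d, A, B, omega, target);
    if (std::fabs(R) > guard || std::fabs(J) > guard ||
        !std::isfinite(R) || !std::isfinite(J))
      stop("trajectory diverged at step %ld (t = %.6f): |state| exceeded guard %g",
           i + 1, t + dt, guard);
  }
  NumericVector times(nr + 1), Rv(nr + 1), Jv(nr + 1);
  double t_rec0 = t0 + (double) nt * dt;
  times[0] = t_rec0; Rv[0] = R; Jv[0] = J;
  for (long i = 0; i < nr; ++i) {
    double t = t_rec0 + (double) i * dt;
    rk4_step(t, dt, R, J, a, b, c, d, A, B, omega, target);
    if (std::fabs(R) > guard || std::fabs(J) > guard ||
        !std::isfinite(R) || !std::isfinite(J))
      stop("trajectory diverged at step %ld (t = %.6f): |state| exceeded guard %g",
           nt + i + 1, t + dt, guard);
    times[i + 1] = t_rec0 + (double)(i + 1) * dt;
    Rv[i + 1] = R; Jv[i + 1] = J;
  }
  return List::create(_["times"] = times, _["R"] = Rv, _["J"] = Jv);
}

// Benettin maximal-exponent loop: co-integrate state and unit tangent,
// renormalize every `steps_per_renorm` steps, accumulate log stretch.
// [[Rcpp::export(name = ".benettin_cpp")]]
List benettin_cpp(double a, double b, double c, double d,
                  double A, double B, double omega, int target,
                  double R0, double J0, double t0, double dt,
                  double n_transient_steps,
                  double steps_per_renorm, double n_renorms,
                  double v0_1, double v0_2, double guard) {
  long nt = (long) n_transient_steps;
  long spr = (long) steps_per_renorm;
  long nren = (long) n_renorms;
  double R = R0, J = J0;
  for (long i = 0; i < nt; ++i) {
    double t = t0 + (double) i * dt;
    rk4_step(t, dt, R, J, a, b, c, d, A, B, omega, target);
    if (std::fabs(R) > guard || std::fabs(J) > guard ||
        !std::isfinite(R) || !std::isfinite(J))
      stop("trajectory diverged at step %ld (t = %.6f): |state| exceeded guard %g",
           i + 1, t + dt, guard);
  }
  double x[4];
  x[0] = R; x[1] = J;
  double nv0 = std::sqrt(v0_1 * v0_1 + v0_2 * v0_2);
  x[2] = v0_1 / nv0; x[3] = v0_2 / nv0;
  NumericVector history(nren);
  double acc = 0.0;
  double t_start = t0 + (double) nt * dt;
  for (long k = 0; k < nren; ++k) {
    for (long i = 0; i < spr; ++i) {
      double t = t_start + (double)(k * spr + i) * dt;
      rk4_step_aug(t, dt, x, a, b, c, d, A, B, omega, target);
      if (std::fabs(x[0]) > guard || std::fabs(x[1]) > guard ||
          !std::isfinite(x[0]) || !std::isfinite(x[1]))
        stop("trajectory diverged at step %ld (t = %.6f): |state| exceeded guard %g",
             nt + k * spr + i + 1, t + dt, guard);
    }
    double nv = std::sqrt(x[2] * x[2] + x[3] * x[3]);
    acc += std::log(nv);
    x[2] /= nv; x[3] /= nv;
    history[k] = acc / ((double)(k + 1) * (double) spr * dt);
  }
  return List::create(_["history"] = history, _["value"] = history[nren - 1],
                      _["final_R"] = x[0], _["final_J"] = x[1]);
}
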
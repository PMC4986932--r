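#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum-of-squares objectives for the identification optimizers. The
// residual is model - data over all traces and sample points; these are
// the hot loops of the Powell-type minimization, so they avoid any R
// allocation.

static inline double boltz(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}
static inline double gtau(double V, double M, double S, double A, double B) {
  double d = (M - V) / S;
  return B + A * std::exp(-d * d);
}

static bool uniform_grid(const NumericVector& t) {
  if (t.size() < 3) return true;
  const double dt = t[1] - t[0];
  for (int i = 2; i < t.size(); ++i)
    if (std::fabs(t[i] - t[i - 1] - dt) > 1e-9 * (1.0 + std::fabs(dt))) return false;
  return true;
}

// add a + b * exp(-t/tau) to model[]; exp by recursion on uniform grids
static void add_exp_decay(std::vector<double>& model, const NumericVector& t,
                          double a, double b, double tau, bool uniform) {
  const int n = t.size();
  if (uniform && n > 1) {
    double e = std::exp(-t[0] / tau);
    const double f = std::exp(-(t[1] - t[0]) / tau);
    for (int i = 0; i < n; ++i) {
      model[i] += a + b * e;
      e *= f;
    }
  } else {
    for (int i = 0; i < n; ++i) model[i] += a + b * std::exp(-t[i] / tau);
  }
}

// theta: 7 per component (Vh, k, M, S, A, B, G)
// obs_act: n_t x n_steps; obs_tail: n_tt x n_steps (0 x 0 to skip)
// [[Rcpp::export]]
double full_trace_ssq(NumericVector theta, NumericVector t_act,
                      NumericVector t_tail, NumericVector vs,
                      double v_hold, double v_post, double t_step, double Eh,
                      NumericMatrix obs_act, NumericMatrix obs_tail) {
  const int ncomp = theta.size() / 7;
  const int nstep = vs.size();
  const int nt = t_act.size();
  const int ntt = obs_tail.nrow() > 0 ? t_tail.size() : 0;
  const bool uni_act = uniform_grid(t_act);
  const bool uni_tail = ntt > 0 ? uniform_grid(t_tail) : true;
  double ssq = 0.0;
  std::vector<double> model(nt);
  std::vector<double> model_tail(ntt > 0 ? ntt : 1);
  for (int j = 0; j < nstep; ++j) {
    std::fill(model.begin(), model.end(), 0.0);
    if (ntt > 0) std::fill(model_tail.begin(), model_tail.end(), 0.0);
    const double drive = vs[j] - Eh;
    const double drive_post = v_post - Eh;
    for (int c = 0; c < ncomp; ++c) {
      const double Vh = theta[7 * c], k = theta[7 * c + 1], M = theta[7 * c + 2],
                   S = theta[7 * c + 3], A = theta[7 * c + 4], B = theta[7 * c + 5],
                   G = theta[7 * c + 6];
      const double r0 = boltz(v_hold, Vh, k);
      const double rinf = boltz(vs[j], Vh, k);
      const double tau = gtau(vs[j], M, S, A, B);
      add_exp_decay(model, t_act, G * rinf * drive, G * (r0 - rinf) * drive,
                    tau, uni_act);
      if (ntt > 0) {
        const double roff = rinf + (r0 - rinf) * std::exp(-t_step / tau);
        const double rinf_p = boltz(v_post, Vh, k);
        const double tau_p = gtau(v_post, M, S, A, B);
        add_exp_decay(model_tail, t_tail, G * rinf_p * drive_post,
                      G * (roff - rinf_p) * drive_post, tau_p, uni_tail);
      }
    }
    for (int i = 0; i < nt; ++i) {
      const double d = model[i] - obs_act(i, j);
      ssq += d * d;
    }
    for (int i = 0; i < ntt; ++i) {
      const double d = model_tail[i] - obs_tail(i, j);
      ssq += d * d;
    }
  }
  return ssq;
}

// theta: 3 per component (G, r, tau); trace model
// I(t) = sum_c G_c r_c (1 - exp(-t/tau_c)) * drive
// [[Rcpp::export]]
double single_trace_ssq(NumericVector theta, NumericVector t, double drive,
                        NumericVector obs) {
  const int ncomp = theta.size() / 3;
  const int nt = t.size();
  const bool uni = uniform_grid(t);
  std::vector<double> model(nt, 0.0);
  for (int c = 0; c < ncomp; ++c) {
    const double amp = theta[3 * c] * theta[3 * c + 1] * drive;
    add_exp_decay(model, t, amp, -amp, theta[3 * c + 2], uni);
  }
  double ssq = 0.0;
  for (int i = 0; i < nt; ++i) {
    const double d = model[i] - obs[i];
    ssq += d * d;
  }
  return ssq;
}
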
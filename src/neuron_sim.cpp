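#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conductance-based single-compartment vestibular ganglion neuron.
// Membrane: C dV/dt = -(INa + IKHT + IKLT + Il + Ihs + Ihf) + Istim with
// every ionic current in the standard convention I = G * gates * (V - E).
// Na/K gating steady states and time constants follow the cochlear-nucleus
// model family (Rothman & Manis 2003 rate equations, 22 C); time constants
// are divided by q_gates for temperature. Ih gates use Boltzmann activation
// and Gaussian kinetics per component, divided by q_ih.

static inline double minf(double V) { return 1.0 / (1.0 + std::exp(-(V + 38.0) / 7.0)); }
static inline double hinf(double V) { return 1.0 / (1.0 + std::exp((V + 65.0) / 6.0)); }
static inline double taum(double V) {
  return 10.0 / (5.0 * std::exp((V + 60.0) / 18.0) + 36.0 * std::exp(-(V + 60.0) / 25.0)) + 0.04;
}
static inline double tauh(double V) {
  return 100.0 / (7.0 * std::exp((V + 60.0) / 11.0) + 10.0 * std::exp(-(V + 60.0) / 25.0)) + 0.6;
}
static inline double ninf(double V) { return std::pow(1.0 + std::exp(-(V + 15.0) / 5.0), -0.5); }
static inline double pinf(double V) { return 1.0 / (1.0 + std::exp(-(V + 23.0) / 6.0)); }
static inline double taun(double V) {
  return 100.0 / (11.0 * std::exp((V + 60.0) / 24.0) + 21.0 * std::exp(-(V + 60.0) / 23.0)) + 0.7;
}
static inline double taup(double V) {
  return 100.0 / (4.0 * std::exp((V + 60.0) / 32.0) + 5.0 * std::exp(-(V + 60.0) / 22.0)) + 5.0;
}
static inline double winf(double V) { return std::pow(1.0 + std::exp(-(V + 48.0) / 6.0), -0.25); }
static inline double zinf(double V) { return 0.5 / (1.0 + std::exp((V + 71.0) / 10.0)) + 0.5; }
static inline double tauw(double V) {
  return 100.0 / (6.0 * std::exp((V + 60.0) / 6.0) + 16.0 * std::exp(-(V + 60.0) / 45.0)) + 1.5;
}
static inline double tauz(double V) {
  return 1000.0 / (std::exp((V + 60.0) / 20.0) + std::exp(-(V + 60.0) / 8.0)) + 50.0;
}

static inline double boltz(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}
static inline double gauss_tau(double V, double M, double S, double A, double B) {
  double d = (M - V) / S;
  return B + A * std::exp(-d * d);
}

// gate update by exponential Euler, clipped to [0, 1]
static inline double gate_step(double x, double xinf, double tau, double dt) {
  double y = xinf + (x - xinf) * std::exp(-dt / tau);
  if (y < 0.0) y = 0.0;
  if (y > 1.0) y = 1.0;
  return y;
}

// [[Rcpp::export]]
NumericVector vgn_steady_gates(double V, NumericVector ih_slow, NumericVector ih_fast) {
  NumericVector g(8);
  g[0] = minf(V); g[1] = hinf(V); g[2] = ninf(V); g[3] = pinf(V);
  g[4] = winf(V); g[5] = zinf(V);
  g[6] = (ih_slow[6] > 0.0) ? boltz(V, ih_slow[0], ih_slow[1]) : 0.0;
  g[7] = (ih_fast[6] > 0.0) ? boltz(V, ih_fast[0], ih_fast[1]) : 0.0;
  return g;
}

// pars: C, GNa, GKH, GKL, Gl, ENa, EK, Eh, El, q_gates, q_ih
// ih_*: Vh, k, M, S, A, B, G
// stim: injected current (pA) per dt step; clamp: commanded V per step
// (NaN = free). Records every `thin` steps (including step 0).
// [[Rcpp::export]]
List vgn_integrate(NumericVector pars, NumericVector ih_slow, NumericVector ih_fast,
                   double v0, NumericVector gates0, double dt,
                   NumericVector stim, NumericVector clamp, int thin,
                   bool record_gates) {
  const double Cm = pars[0], GNa = pars[1], GKH = pars[2], GKL = pars[3],
               Gl = pars[4], ENa = pars[5], EK = pars[6], Eh = pars[7],
               El = pars[8], qg = pars[9], qih = pars[10];
  const int n = stim.size();
  const int nrec = n / thin + 1;
  NumericVector Vout(nrec), tout(nrec);
  NumericMatrix gout = record_gates ? NumericMatrix(nrec, 8) : NumericMatrix(1, 1);

  double V = v0;
  double m = gates0[0], h = gates0[1], nn = gates0[2], p = gates0[3],
         w = gates0[4], z = gates0[5], rs = gates0[6], rf = gates0[7];
  const bool has_slow = ih_slow[6] > 0.0, has_fast = ih_fast[6] > 0.0;

  int irec = 0;
  for (int i = 0; i <= n; ++i) {
    if (i % thin == 0 && irec < nrec) {
      Vout[irec] = V;
      tout[irec] = i * dt;
      if (record_gates) {
        gout(irec, 0) = m; gout(irec, 1) = h; gout(irec, 2) = nn; gout(irec, 3) = p;
        gout(irec, 4) = w; gout(irec, 5) = z; gout(irec, 6) = rs; gout(irec, 7) = rf;
      }
      ++irec;
    }
    if (i == n) break;

    // gate updates at the current voltage
    m  = gate_step(m,  minf(V), taum(V) / qg, dt);
    h  = gate_step(h,  hinf(V), tauh(V) / qg, dt);
    nn = gate_step(nn, ninf(V), taun(V) / qg, dt);
    p  = gate_step(p,  pinf(V), taup(V) / qg, dt);
    w  = gate_step(w,  winf(V), tauw(V) / qg, dt);
    z  = gate_step(z,  zinf(V), tauz(V) / qg, dt);
    if (has_slow)
      rs = gate_step(rs, boltz(V, ih_slow[0], ih_slow[1]),
                     gauss_tau(V, ih_slow[2], ih_slow[3], ih_slow[4], ih_slow[5]) / qih, dt);
    if (has_fast)
      rf = gate_step(rf, boltz(V, ih_fast[0], ih_fast[1]),
                     gauss_tau(V, ih_fast[2], ih_fast[3], ih_fast[4], ih_fast[5]) / qih, dt);

    if (R_finite(clamp[i])) {
      V = clamp[i];
      continue;
    }

    // membrane update by exponential Euler on the instantaneous
    // conductances
    double gNa = GNa * m * m * m * h;
    double gKH = GKH * (0.85 * nn * nn + 0.15 * p);
    double gKL = GKL * w * w * w * w * z;
    double gHs = has_slow ? ih_slow[6] * rs : 0.0;
    double gHf = has_fast ? ih_fast[6] * rf : 0.0;
    double gtot = gNa + gKH + gKL + Gl + gHs + gHf;
    double isum = gNa * ENa + (gKH + gKL) * EK + Gl * El + (gHs + gHf) * Eh + stim[i];
    double Vinf = isum / gtot;
    V = Vinf + (V - Vinf) * std::exp(-dt * gtot / Cm);
    if (!R_finite(V)) stop("integration diverged; reduce dt");
  }
  List out = List::create(_["t"] = tout, _["V"] = Vout);
  if (record_gates) out["gates"] = gout;
  return out;
}
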
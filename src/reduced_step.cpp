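#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Semi-implicit stepper for the reduced half-sarcomere model.
//
// State layout (rows): Vm, m, h, n, Ca, A1, A2.
// Scheme per step: exponential (Rush-Larsen) gate update with rates frozen
// at the current voltage; linearized-implicit voltage update with
// conductances from the new gates; implicit linear calcium update; implicit
// 2x2 crossbridge update. Every sub-update is unconditionally stable and
// positivity preserving for the linear subsystems.
//
// par order: gNa, ENa, gK, EK, gL, EL, k_rel, V_rel, k_slope, k_up,
//            k_att, K_ca, k_det, f_p, f_m, g_d
//
// stim_nodes: 0-based column indices receiving an applied membrane current;
// stim_vals: n_steps x length(stim_nodes) applied current (uA/cm^2, sign
// convention dV/dt = -(I_ion + I_app)/Cm, so depolarizing pulses are
// negative).

static inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}

// [[Rcpp::export]]
List reduced_step_cpp(NumericMatrix states, double dt, int n_steps,
                      double Cm, NumericVector par,
                      IntegerVector stim_nodes, NumericMatrix stim_vals,
                      bool record) {
  if (states.nrow() != 7) stop("states must have 7 rows");
  const int nc = states.ncol();
  const double gNa = par[0], ENa = par[1], gK = par[2], EK = par[3],
               gL = par[4], EL = par[5], krel = par[6], Vrel = par[7],
               kslope = par[8], kup = par[9], katt = par[10], Kca = par[11],
               kdet = par[12], fp = par[13], fm = par[14], gd = par[15];
  NumericMatrix S = clone(states);
  const int nstim = stim_nodes.size();
  NumericMatrix trace;
  if (record) {
    if (nc != 1) stop("record = TRUE requires a single cell");
    trace = NumericMatrix(n_steps, 4); // Vm, Ca, A1, A2
  }

  std::vector<double> iapp(nc, 0.0);
  for (int k = 0; k < n_steps; ++k) {
    for (int s = 0; s < nstim; ++s) iapp[stim_nodes[s]] = stim_vals(k, s);
    for (int j = 0; j < nc; ++j) {
      double V = S(0, j), m = S(1, j), h = S(2, j), n = S(3, j),
             Ca = S(4, j), A1 = S(5, j), A2 = S(6, j);

      // gates (exact exponential update at frozen V)
      double am = alpha_m(V), bm = 4.0 * std::exp(-(V + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(V + 65.0) / 20.0),
             bh = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
      double an = alpha_n(V), bn = 0.125 * std::exp(-(V + 65.0) / 80.0);
      double sm = am + bm, sh = ah + bh, sn = an + bn;
      m = am / sm + (m - am / sm) * std::exp(-dt * sm);
      h = ah / sh + (h - ah / sh) * std::exp(-dt * sh);
      n = an / sn + (n - an / sn) * std::exp(-dt * sn);

      // voltage (implicit in V with conductances from the new gates)
      double gna = gNa * m * m * m * h, gk = gK * n * n * n * n;
      double gtot = gna + gk + gL;
      double drive = gna * ENa + gk * EK + gL * EL - iapp[j];
      V = (V + dt / Cm * drive) / (1.0 + dt / Cm * gtot);

      // calcium (linear implicit given V)
      double srel = 1.0 / (1.0 + std::exp(-(V - Vrel) / kslope));
      Ca = (Ca + dt * krel * srel) / (1.0 + dt * (krel * srel + kup));

      // crossbridge pools (implicit 2x2 given Ca)
      double hc = Ca * Ca / (Ca * Ca + Kca * Kca);
      double r1 = katt * hc;
      double a11 = 1.0 + dt * (r1 + kdet + fp), a12 = dt * (r1 - fm);
      double a21 = -dt * fp, a22 = 1.0 + dt * (fm + gd);
      double det = a11 * a22 - a12 * a21;
      double b1 = A1 + dt * r1, b2 = A2;
      A1 = (a22 * b1 - a12 * b2) / det;
      A2 = (a11 * b2 - a21 * b1) / det;

      if (!std::isfinite(V) || !std::isfinite(Ca) || !std::isfinite(A2))
        stop("cell-model solver divergence at cell %d, substep %d", j + 1, k + 1);

      S(0, j) = V; S(1, j) = m; S(2, j) = h; S(3, j) = n;
      S(4, j) = Ca; S(5, j) = A1; S(6, j) = A2;
      if (record) {
        trace(k, 0) = V; trace(k, 1) = Ca; trace(k, 2) = A1; trace(k, 3) = A2;
      }
    }
  }
  if (record) return List::create(_["states"] = S, _["trace"] = trace);
  return List::create(_["states"] = S);
}
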
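#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Excitatory transfer (aI - b) / (1 - exp(-d (aI - b))), continuous at aI = b.
static inline double phi_exc(double I, double a, double b, double d) {
  double x = a * I - b;
  if (x == 0.0) return 1.0 / d;
  double den = -expm1(-d * x);
  return x / den;
}

// Inhibitory transfer (c1 I - c0)/gI + r0, rectified at zero rate.
static inline double phi_inh(double I, double gI, double c1, double c0, double r0) {
  double v = (c1 * I - c0 + gI * r0) / gI;
  return v > 0.0 ? v : 0.0;
}

struct Pars {
  double tauN, tauG, gamma, gammaI, Jc, JEI, JII, I0A, I0B, I0C;
  double a, b, d, gI, c1, c0, r0, taur, taunoise, sigA, sigB, sigC;
  NumericVector Js, JIE;
};

static Pars unpack(const List& par) {
  Pars p;
  p.tauN = par["tau_N"]; p.tauG = par["tau_G"];
  p.gamma = par["gamma"]; p.gammaI = par["gamma_I"];
  p.Jc = par["J_c"]; p.JEI = par["J_EI"]; p.JII = par["J_II"];
  p.I0A = par["I0_A"]; p.I0B = par["I0_B"]; p.I0C = par["I0_C"];
  p.a = par["a"]; p.b = par["b"]; p.d = par["d"];
  p.gI = par["g_I"]; p.c1 = par["c1"]; p.c0 = par["c0"]; p.r0 = par["r0"];
  p.taur = par["tau_r"]; p.taunoise = par["tau_noise"];
  p.sigA = par["sigma_A"]; p.sigB = par["sigma_B"]; p.sigC = par["sigma_C"];
  p.Js = par["Js_vec"]; p.JIE = par["JIE_vec"];
  return p;
}

// Core Euler-Maruyama integrator for the coupled N-area network.
//
// state0: N x 9 matrix, columns (S_A, S_B, S_C, r_A, r_B, r_C, x_A, x_B, x_C).
// WEE, WEI: N x N effective long-range weights (rows = target), already
//   carrying the FLN rescaling, target-side gradient and SLN / (1-SLN) CIB
//   factors. G and Z are applied here.
// events: k x 5 matrix (area0, pop{0,1,2}, on_step, off_step, amplitude nA).
// silence: m x 3 matrix (area0, on_step, off_step); clamped areas have all
//   state zeroed so they neither fire nor transmit.
// record_every <= 0 records nothing (final state only).
// If relax_tol > 0 the integration stops early once the max absolute rate
// change per check interval drops below relax_tol (deterministic runs only).
// [[Rcpp::export]]
List sim_network_cpp(NumericMatrix state0, List par,
                     NumericMatrix WEE, NumericMatrix WEI,
                     double G, double Z,
                     NumericMatrix events, NumericMatrix silence,
                     double dt, int n_steps, int record_every,
                     bool deterministic,
                     double relax_tol, int check_every) {
  const int N = state0.nrow();
  Pars p = unpack(par);
  std::vector<double> SA(N), SB(N), SC(N), rA(N), rB(N), rC(N),
      xA(N), xB(N), xC(N);
  for (int i = 0; i < N; ++i) {
    SA[i] = state0(i, 0); SB[i] = state0(i, 1); SC[i] = state0(i, 2);
    rA[i] = state0(i, 3); rB[i] = state0(i, 4); rC[i] = state0(i, 5);
    xA[i] = state0(i, 6); xB[i] = state0(i, 7); xC[i] = state0(i, 8);
  }
  const int n_rec = record_every > 0 ? n_steps / record_every : 0;
  NumericMatrix recA(n_rec, N), recB(n_rec, N), recC(n_rec, N);
  NumericVector rec_t(n_rec);

  std::vector<int> sil(N, 0);
  std::vector<double> prevA(rA), prevB(rB);
  const double sqdt = std::sqrt(dt);
  bool unstable = false, converged = false;
  long n_clip = 0;
  int step_stop = n_steps;

  for (int s = 0; s < n_steps; ++s) {
    // silencing mask for this step
    for (int i = 0; i < N; ++i) sil[i] = 0;
    for (int e = 0; e < silence.nrow(); ++e) {
      if (s >= silence(e, 1) && s < silence(e, 2)) sil[(int)silence(e, 0)] = 1;
    }
    for (int i = 0; i < N; ++i) {
      if (sil[i]) {
        SA[i] = SB[i] = SC[i] = 0.0;
        rA[i] = rB[i] = rC[i] = 0.0;
        xA[i] = xB[i] = xC[i] = 0.0;
      }
    }
    // long-range inputs
    std::vector<double> InA(N, 0.0), InB(N, 0.0), InC(N, 0.0);
    if (G != 0.0) {
      for (int x = 0; x < N; ++x) {
        double sa = 0.0, sb = 0.0, si = 0.0;
        for (int y = 0; y < N; ++y) {
          sa += WEE(x, y) * SA[y];
          sb += WEE(x, y) * SB[y];
          si += WEI(x, y) * (SA[y] + SB[y]);
        }
        InA[x] = G * sa; InB[x] = G * sb; InC[x] = G * Z * si;
      }
    }
    // stimulus currents
    std::vector<double> stA(N, 0.0), stB(N, 0.0), stC(N, 0.0);
    for (int e = 0; e < events.nrow(); ++e) {
      if (s >= events(e, 2) && s < events(e, 3)) {
        int i = (int)events(e, 0), pop = (int)events(e, 1);
        if (pop == 0) stA[i] += events(e, 4);
        else if (pop == 1) stB[i] += events(e, 4);
        else stC[i] += events(e, 4);
      }
    }
    // state update
    for (int i = 0; i < N; ++i) {
      if (sil[i]) continue;
      double IA = p.Js[i] * SA[i] + p.Jc * SB[i] + p.JEI * SC[i] + p.I0A +
                  InA[i] + stA[i] + xA[i];
      double IB = p.Jc * SA[i] + p.Js[i] * SB[i] + p.JEI * SC[i] + p.I0B +
                  InB[i] + stB[i] + xB[i];
      double IC = p.JIE[i] * (SA[i] + SB[i]) + p.JII * SC[i] + p.I0C +
                  InC[i] + stC[i] + xC[i];
      double fA = phi_exc(IA, p.a, p.b, p.d);
      double fB = phi_exc(IB, p.a, p.b, p.d);
      double fC = phi_inh(IC, p.gI, p.c1, p.c0, p.r0);

      double dSA = dt * (-SA[i] / p.tauN + p.gamma * (1.0 - SA[i]) * rA[i]);
      double dSB = dt * (-SB[i] / p.tauN + p.gamma * (1.0 - SB[i]) * rB[i]);
      double dSC = dt * (-SC[i] / p.tauG + p.gammaI * rC[i]);
      if (std::fabs(dSA) > 0.2 || std::fabs(dSB) > 0.2) unstable = true;
      SA[i] += dSA; SB[i] += dSB; SC[i] += dSC;
      if (SA[i] < 0.0) { SA[i] = 0.0; ++n_clip; }
      if (SA[i] > 1.0) { SA[i] = 1.0; ++n_clip; }
      if (SB[i] < 0.0) { SB[i] = 0.0; ++n_clip; }
      if (SB[i] > 1.0) { SB[i] = 1.0; ++n_clip; }
      if (SC[i] < 0.0) SC[i] = 0.0;

      rA[i] += dt / p.taur * (fA - rA[i]);
      rB[i] += dt / p.taur * (fB - rB[i]);
      rC[i] += dt / p.taur * (fC - rC[i]);
      if (rA[i] < 0.0) rA[i] = 0.0;
      if (rB[i] < 0.0) rB[i] = 0.0;
      if (rC[i] < 0.0) rC[i] = 0.0;

      if (!deterministic) {
        xA[i] += dt * (-xA[i] / p.taunoise) + p.sigA * sqdt * norm_rand();
        xB[i] += dt * (-xB[i] / p.taunoise) + p.sigB * sqdt * norm_rand();
        xC[i] += dt * (-xC[i] / p.taunoise) + p.sigC * sqdt * norm_rand();
      }
    }
    if (unstable) { step_stop = s + 1; break; }
    if (record_every > 0 && (s + 1) % record_every == 0) {
      int k = (s + 1) / record_every - 1;
      rec_t[k] = (s + 1) * dt;
      for (int i = 0; i < N; ++i) {
        recA(k, i) = rA[i]; recB(k, i) = rB[i]; recC(k, i) = rC[i];
      }
    }
    if (relax_tol > 0.0 && (s + 1) % check_every == 0) {
      double dmax = 0.0;
      for (int i = 0; i < N; ++i) {
        dmax = std::max(dmax, std::fabs(rA[i] - prevA[i]));
        dmax = std::max(dmax, std::fabs(rB[i] - prevB[i]));
      }
      prevA = rA; prevB = rB;
      if (dmax < relax_tol) { converged = true; step_stop = s + 1; break; }
    }
  }

  NumericMatrix fin(N, 9);
  for (int i = 0; i < N; ++i) {
    fin(i, 0) = SA[i]; fin(i, 1) = SB[i]; fin(i, 2) = SC[i];
    fin(i, 3) = rA[i]; fin(i, 4) = rB[i]; fin(i, 5) = rC[i];
    fin(i, 6) = xA[i]; fin(i, 7) = xB[i]; fin(i, 8) = xC[i];
  }
  return List::create(_["rA"] = recA, _["rB"] = recB, _["rC"] = recC,
                      _["time"] = rec_t, _["final"] = fin,
                      _["unstable"] = unstable, _["converged"] = converged,
                      _["n_clip"] = n_clip, _["steps_run"] = step_stop);
}
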
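// Fixed-step RK4 integration of the conductance-based membrane model and a
// hybrid Gillespie realization with discrete Markov channels.
//
// Parameter vector layout (built by .param_vec() on the R side):
//  0 Cin  1 Gin  2 Vr  3 I  4 ENa  5 EK  6 GNat  7 GNap  8 GKdr  9 GA
// 10 Vm  11 km  12 taum  13 Vh  14 kh
// 15 Vmp 16 kmp 17 taump 18 Vs  19 ks  20 taus
// 21 Vn  22 kn  23 taun  24 VmA 25 kmA 26 VhA 27 khA 28 tauhA
// 29-32 tau_h(V) coefficients  33 slow-inactivation flag  34 IA flag
//
// State layout: x[0]=V x[1]=m x[2]=h x[3]=mp x[4]=s x[5]=n x[6]=hA
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sig(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}

struct Pars {
  double Cin, Gin, Vr, I, ENa, EK, GNat, GNap, GKdr, GA;
  double Vm, km, taum, Vh, kh, Vmp, kmp, taump, Vs, ks, taus;
  double Vn, kn, taun, VmA, kmA, VhA, khA, tauhA;
  double th1, th2, th3, th4;
  bool slow, ia;
  explicit Pars(const NumericVector& p) {
    Cin = p[0]; Gin = p[1]; Vr = p[2]; I = p[3]; ENa = p[4]; EK = p[5];
    GNat = p[6]; GNap = p[7]; GKdr = p[8]; GA = p[9];
    Vm = p[10]; km = p[11]; taum = p[12]; Vh = p[13]; kh = p[14];
    Vmp = p[15]; kmp = p[16]; taump = p[17]; Vs = p[18]; ks = p[19];
    taus = p[20]; Vn = p[21]; kn = p[22]; taun = p[23];
    VmA = p[24]; kmA = p[25]; VhA = p[26]; khA = p[27]; tauhA = p[28];
    th1 = p[29]; th2 = p[30]; th3 = p[31]; th4 = p[32];
    slow = p[33] != 0; ia = p[34] != 0;
  }
  double tauh(double V) const { return th1 - th2 * std::tanh((V + th3) / th4); }
};

// dx/dt in current-clamp mode; Icmd is the injected current (pA)
static void deriv(const Pars& P, const double* x, double Icmd, double* dx) {
  const double V = x[0];
  const double m3h = x[1] * x[1] * x[1] * x[2];
  const double mp3s = x[3] * x[3] * x[3] * x[4];
  const double n3 = x[5] * x[5] * x[5];
  double IV = P.Gin * (P.Vr - V) + P.GNat * m3h * (P.ENa - V) +
              P.GNap * mp3s * (P.ENa - V) + P.GKdr * n3 * (P.EK - V) + Icmd;
  if (P.ia)
    IV += P.GA * sig(V, P.VmA, P.kmA) * x[6] * (P.EK - V);
  dx[0] = IV / P.Cin;
  dx[1] = (sig(V, P.Vm, P.km) - x[1]) / P.taum;
  dx[2] = (sig(V, P.Vh, P.kh) - x[2]) / P.tauh(V);
  dx[3] = (sig(V, P.Vmp, P.kmp) - x[3]) / P.taump;
  dx[4] = P.slow ? (sig(V, P.Vs, P.ks) - x[4]) / P.taus : 0.0;
  dx[5] = (sig(V, P.Vn, P.kn) - x[5]) / P.taun;
  dx[6] = P.ia ? (sig(V, P.VhA, P.khA) - x[6]) / P.tauhA : 0.0;
}

// gate derivatives only, with V imposed (voltage clamp)
static void deriv_gates(const Pars& P, const double* x, double V, double* dx) {
  dx[0] = 0.0;
  dx[1] = (sig(V, P.Vm, P.km) - x[1]) / P.taum;
  dx[2] = (sig(V, P.Vh, P.kh) - x[2]) / P.tauh(V);
  dx[3] = (sig(V, P.Vmp, P.kmp) - x[3]) / P.taump;
  dx[4] = P.slow ? (sig(V, P.Vs, P.ks) - x[4]) / P.taus : 0.0;
  dx[5] = (sig(V, P.Vn, P.kn) - x[5]) / P.taun;
  dx[6] = P.ia ? (sig(V, P.VhA, P.khA) - x[6]) / P.tauhA : 0.0;
}

// command value at time t inside segment seg (linear in t between c0 and c1)
static inline double cmd_at(const NumericMatrix& seg, int k, double tloc) {
  const double dur = seg(k, 0);
  return seg(k, 1) + (seg(k, 2) - seg(k, 1)) * (dur > 0 ? tloc / dur : 0.0);
}

// [[Rcpp::export]]
List rcpp_integrate(NumericVector pvec, NumericMatrix segments, int mode,
                    double dt, NumericVector x0, int record_every) {
  Pars P(pvec);
  const int nseg = segments.nrow();
  double x[7];
  for (int i = 0; i < 7; ++i) x[i] = x0[i];

  double total = 0.0;
  for (int k = 0; k < nseg; ++k) total += segments(k, 0);
  const long nstep = (long)std::llround(total / dt);
  const long nrec = nstep / record_every + 2;

  NumericVector t_out(nrec), V_out(nrec), cmd_out(nrec), s_out(nrec);
  NumericVector iL(mode == 1 ? nrec : 0), iNat(mode == 1 ? nrec : 0),
      iNap(mode == 1 ? nrec : 0), iK(mode == 1 ? nrec : 0),
      iA(mode == 1 ? nrec : 0);

  double k1[7], k2[7], k3[7], k4[7], xt[7];
  long idx = 0, rec = 0;
  double t = 0.0;
  int seg = 0;
  double seg_t0 = 0.0;

  auto record = [&](double tt, double cmd) {
    t_out[rec] = tt; V_out[rec] = x[0]; cmd_out[rec] = cmd; s_out[rec] = x[4];
    if (mode == 1) {
      const double V = x[0];
      iL[rec] = P.Gin * (V - P.Vr);
      iNat[rec] = P.GNat * x[1] * x[1] * x[1] * x[2] * (V - P.ENa);
      iNap[rec] = P.GNap * x[3] * x[3] * x[3] * x[4] * (V - P.ENa);
      iK[rec] = P.GKdr * x[5] * x[5] * x[5] * (V - P.EK);
      iA[rec] = P.ia ? P.GA * sig(V, P.VmA, P.kmA) * x[6] * (V - P.EK) : 0.0;
    }
    ++rec;
  };

  for (long step = 0; step < nstep; ++step) {
    t = step * dt;  // avoid accumulation error at segment boundaries
    while (seg < nseg - 1 && t - seg_t0 >= segments(seg, 0) - dt / 2) {
      seg_t0 += segments(seg, 0);
      ++seg;
    }
    const double c0 = cmd_at(segments, seg, t - seg_t0);
    const double ch = cmd_at(segments, seg, t - seg_t0 + dt / 2);
    const double c1 = cmd_at(segments, seg, t - seg_t0 + dt);

    if (step % record_every == 0) {
      if (mode == 1) x[0] = c0;
      record(t, c0);
    }

    if (mode == 0) {  // current clamp
      deriv(P, x, c0, k1);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt / 2 * k1[i];
      deriv(P, xt, ch, k2);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt / 2 * k2[i];
      deriv(P, xt, ch, k3);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt * k3[i];
      deriv(P, xt, c1, k4);
      for (int i = 0; i < 7; ++i)
        x[i] += dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    } else {  // ideal voltage clamp: V follows the command exactly
      x[0] = c0;
      deriv_gates(P, x, c0, k1);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt / 2 * k1[i];
      deriv_gates(P, xt, ch, k2);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt / 2 * k2[i];
      deriv_gates(P, xt, ch, k3);
      for (int i = 0; i < 7; ++i) xt[i] = x[i] + dt * k3[i];
      deriv_gates(P, xt, c1, k4);
      for (int i = 1; i < 7; ++i)
        x[i] += dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      x[0] = c1;
    }
    if (!std::isfinite(x[0]))
      stop("integration diverged (non-finite V at t = %f ms); reduce dt", t);
    ++idx;
  }
  t = nstep * dt;
  {  // final sample
    const double cend = segments(nseg - 1, 2);
    if (mode == 1) x[0] = cend;
    record(t, cend);
  }

  NumericVector xf(7);
  for (int i = 0; i < 7; ++i) xf[i] = x[i];
  List out = List::create(
      _["t"] = t_out[Range(0, rec - 1)], _["V"] = V_out[Range(0, rec - 1)],
      _["cmd"] = cmd_out[Range(0, rec - 1)], _["s"] = s_out[Range(0, rec - 1)],
      _["final_state"] = xf);
  if (mode == 1) {
    out["I_leak"] = iL[Range(0, rec - 1)];
    out["I_Nat"] = iNat[Range(0, rec - 1)];
    out["I_Nap"] = iNap[Range(0, rec - 1)];
    out["I_Kdr"] = iK[Range(0, rec - 1)];
    out["I_A"] = iA[Range(0, rec - 1)];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hybrid Gillespie channel-noise simulation (current clamp only).
//
// Channel populations: Nat N = round(GNat/gamma), 8-state m^3 h scheme;
// Nap N = round(GNap/gamma), mp (4-state) x s (2-state), channel open iff
// all three mp subunits open AND s open; Kdr N = round(GKdr/gamma), 4-state
// n^3. Per-subunit rates alpha = xinf(V)/tau, beta = (1-xinf(V))/tau.
// Voltage relaxes exactly (linear ODE with frozen conductances) between
// transitions; rates are refreshed after every voltage advance and at least
// every dt_max ms.

struct Counts {
  // nat[i][j]: i open m subunits (0..3), j = h state (0 inactivated, 1 open)
  long nat[4][2];
  long nap[4][2];  // mp x s
  long kdr[4];     // open n subunits
};

// [[Rcpp::export]]
List rcpp_gillespie(NumericVector pvec, NumericMatrix segments, double gamma,
                    double dt_max, double record_dt, NumericVector x0) {
  Pars P(pvec);
  if (P.ia) stop("channel-noise simulation does not include the A-current");
  RNGScope scope;

  const long Nnat = (long)std::llround(P.GNat / gamma);
  const long Nnap = (long)std::llround(P.GNap / gamma);
  const long Nkdr = (long)std::llround(P.GKdr / gamma);

  double V = x0[0];
  Counts C;
  // initialize occupancies from the steady-state product distribution at V
  {
    double minf = sig(V, P.Vm, P.km), hinf = sig(V, P.Vh, P.kh);
    double mpinf = sig(V, P.Vmp, P.kmp);
    double sinf = P.slow ? sig(V, P.Vs, P.ks) : 1.0;
    double ninf = sig(V, P.Vn, P.kn);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 2; ++j) { C.nat[i][j] = 0; C.nap[i][j] = 0; }
    for (int i = 0; i < 4; ++i) C.kdr[i] = 0;
    for (long c = 0; c < Nnat; ++c) {
      int i = (int)R::rbinom(3, minf), j = (R::unif_rand() < hinf) ? 1 : 0;
      ++C.nat[i][j];
    }
    for (long c = 0; c < Nnap; ++c) {
      int i = (int)R::rbinom(3, mpinf), j = (R::unif_rand() < sinf) ? 1 : 0;
      ++C.nap[i][j];
    }
    for (long c = 0; c < Nkdr; ++c) ++C.kdr[(int)R::rbinom(3, ninf)];
  }

  const int nseg = segments.nrow();
  double total = 0.0;
  for (int k = 0; k < nseg; ++k) total += segments(k, 0);
  const long nrec = (long)(total / record_dt) + 2;
  NumericVector t_out(nrec), V_out(nrec), cmd_out(nrec), s_out(nrec);
  long rec = 0;
  double next_rec = 0.0;

  double t = 0.0;
  int seg = 0;
  double seg_t0 = 0.0;

  // transition table: up to 46 reaction channels, rebuilt at each refresh
  double rate[64];
  int kind[64];

  while (t < total - 1e-9) {
    while (seg < nseg - 1 && t - seg_t0 >= segments(seg, 0) - 1e-12) {
      seg_t0 += segments(seg, 0);
      ++seg;
    }
    const double Icmd = cmd_at(segments, seg, t - seg_t0);

    // per-subunit rates at current V
    const double am = sig(V, P.Vm, P.km) / P.taum,
                 bm = (1 - sig(V, P.Vm, P.km)) / P.taum;
    const double th = P.tauh(V);
    const double ah = sig(V, P.Vh, P.kh) / th,
                 bh = (1 - sig(V, P.Vh, P.kh)) / th;
    const double ap = sig(V, P.Vmp, P.kmp) / P.taump,
                 bp = (1 - sig(V, P.Vmp, P.kmp)) / P.taump;
    const double as = P.slow ? sig(V, P.Vs, P.ks) / P.taus : 0.0,
                 bs = P.slow ? (1 - sig(V, P.Vs, P.ks)) / P.taus : 0.0;
    const double an = sig(V, P.Vn, P.kn) / P.taun,
                 bn = (1 - sig(V, P.Vn, P.kn)) / P.taun;

    int nr = 0;
    double tot = 0.0;
    // Nat: m up/down and h flips per (i,j) cell
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 2; ++j) {
        long c = C.nat[i][j];
        if (!c) continue;
        if (i < 3) { rate[nr] = c * (3 - i) * am; kind[nr] = 100 + i * 10 + j; tot += rate[nr]; ++nr; }
        if (i > 0) { rate[nr] = c * i * bm; kind[nr] = 200 + i * 10 + j; tot += rate[nr]; ++nr; }
        rate[nr] = c * (j ? bh : ah); kind[nr] = 300 + i * 10 + j; tot += rate[nr]; ++nr;
      }
    // Nap: mp up/down and s flips
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 2; ++j) {
        long c = C.nap[i][j];
        if (!c) continue;
        if (i < 3) { rate[nr] = c * (3 - i) * ap; kind[nr] = 400 + i * 10 + j; tot += rate[nr]; ++nr; }
        if (i > 0) { rate[nr] = c * i * bp; kind[nr] = 500 + i * 10 + j; tot += rate[nr]; ++nr; }
        if (P.slow) { rate[nr] = c * (j ? bs : as); kind[nr] = 600 + i * 10 + j; tot += rate[nr]; ++nr; }
      }
    // Kdr: n up/down
    for (int i = 0; i < 4; ++i) {
      long c = C.kdr[i];
      if (!c) continue;
      if (i < 3) { rate[nr] = c * (3 - i) * an; kind[nr] = 700 + i; tot += rate[nr]; ++nr; }
      if (i > 0) { rate[nr] = c * i * bn; kind[nr] = 800 + i; tot += rate[nr]; ++nr; }
    }

    double dt_e = (tot > 0) ? R::exp_rand() / tot : R_PosInf;
    double adv = std::min(dt_e, dt_max);
    adv = std::min(adv, total - t);

    // exact voltage relaxation with frozen conductances over adv
    {
      const double gNat = gamma * C.nat[3][1];
      const double gNap = gamma * C.nap[3][1];
      const double gK = gamma * C.kdr[3];
      const double G = P.Gin + gNat + gNap + gK;
      const double Vinf =
          (P.Gin * P.Vr + (gNat + gNap) * P.ENa + gK * P.EK + Icmd) / G;
      V = Vinf + (V - Vinf) * std::exp(-G * adv / P.Cin);
    }

    while (t + adv >= next_rec - 1e-12 && rec < nrec) {
      t_out[rec] = next_rec; V_out[rec] = V; cmd_out[rec] = Icmd;
      {
        long so = 0;
        for (int i = 0; i < 4; ++i) so += C.nap[i][1];
        s_out[rec] = Nnap ? (double)so / Nnap : 1.0;
      }
      ++rec;
      next_rec += record_dt;
    }
    t += adv;

    if (dt_e <= dt_max && tot > 0 && t < total - 1e-9) {
      // pick and apply one transition
      double u = R::unif_rand() * tot, acc = 0.0;
      int pick = nr - 1;
      for (int q = 0; q < nr; ++q) {
        acc += rate[q];
        if (u <= acc) { pick = q; break; }
      }
      const int kd = kind[pick];
      const int base = kd / 100, i = (kd % 100) / 10, j = kd % 10;
      switch (base) {
        case 1: --C.nat[i][j]; ++C.nat[i + 1][j]; break;
        case 2: --C.nat[i][j]; ++C.nat[i - 1][j]; break;
        case 3: --C.nat[i][j]; ++C.nat[i][1 - j]; break;
        case 4: --C.nap[i][j]; ++C.nap[i + 1][j]; break;
        case 5: --C.nap[i][j]; ++C.nap[i - 1][j]; break;
        case 6: --C.nap[i][j]; ++C.nap[i][1 - j]; break;
        case 7: { int ii = kd % 100; --C.kdr[ii]; ++C.kdr[ii + 1]; } break;
        case 8: { int ii = kd % 100; --C.kdr[ii]; ++C.kdr[ii - 1]; } break;
      }
    }
    if (!std::isfinite(V)) stop("stochastic simulation diverged at t = %f", t);
  }

  return List::create(
      _["t"] = t_out[Range(0, rec - 1)], _["V"] = V_out[Range(0, rec - 1)],
      _["cmd"] = cmd_out[Range(0, rec - 1)], _["s"] = s_out[Range(0, rec - 1)],
      _["n_channels"] = NumericVector::create(
          _["Nat"] = (double)Nnat, _["Nap"] = (double)Nnap,
          _["Kdr"] = (double)Nkdr));
}
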
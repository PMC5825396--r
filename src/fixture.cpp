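// Reduced ventricular-type cell model shared by the two fixture cell types,
// plus a specialised adaptive Dormand-Prince 5(4) integrator.
//
// The model keeps intracellular Na+ and K+ fixed so that the only slow state
// is Ca2+ cycling; all 13 ion-transport pathways appear as separable maximal
// rate factors.  States (9):
//   0 V     membrane potential (mV)
//   1 h     I_Na inactivation gate
//   2 d     I_CaL activation gate
//   3 f     I_CaL voltage-dependent inactivation gate
//   4 r     I_to inactivation gate
//   5 xr    I_Kr activation gate
//   6 xs    I_Ks activation gate
//   7 Cai   cytosolic [Ca2+] (mM)
//   8 CaSR  sarcoplasmic-reticulum [Ca2+] (mM)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_STATE = 9;

// parameter vector layout (see R/cell_models.R, must stay in sync)
enum {
  P_GNa = 0, P_GK1, P_GKr, P_GKs, P_Gto, P_GCaL, P_KNCX, P_KNaK,
  P_GpCa, P_GbNa, P_GbCa, P_KRyR, P_KSERCA,
  P_Nao, P_Cao, P_Ko, P_Nai, P_Ki,
  P_conv, P_vsr, P_Kmup, P_kleak, P_Bmax, P_Kdbuf,
  P_tauf, P_tauxr,
  N_PAR
};

static const double RTF = 26.712338;  // RT/F at 310 K, mV

static inline void rhs(double t, const double* y, double* dy,
                       const double* p, double istim) {
  (void)t;
  const double V = y[0], h = y[1], d = y[2], f = y[3], r = y[4];
  const double xr = y[5], xs = y[6];
  double Cai = y[7], CaSR = y[8];
  if (Cai < 1e-8) Cai = 1e-8;
  if (CaSR < 1e-6) CaSR = 1e-6;

  const double Nao = p[P_Nao], Cao = p[P_Cao], Ko = p[P_Ko];
  const double Nai = p[P_Nai], Ki = p[P_Ki];

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK  = RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  // fast Na+ current: instantaneous activation, single inactivation gate
  const double minf = 1.0 / (1.0 + std::exp(-(V + 45.0) / 5.5));
  const double INa = p[P_GNa] * minf * minf * minf * h * (V - ENa);
  const double hinf = 1.0 / (1.0 + std::exp((V + 70.0) / 6.5));
  const double tauh = 1.0 + 14.0 / (1.0 + std::exp((V + 60.0) / 8.0));

  // L-type Ca2+ current, GHK-type driving force (linear in Cao)
  const double dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 6.5));
  const double taud = 0.8 + 2.5 * std::exp(-(V + 25.0) * (V + 25.0) / 400.0);
  const double finf = 1.0 / (1.0 + std::exp((V + 27.0) / 7.0));
  const double tauf = p[P_tauf] *
      (30.0 + 250.0 / (1.0 + std::exp(-(V + 25.0) / 5.0)));
  const double fca = 1.0 / (1.0 + (Cai / 0.0015) * (Cai / 0.0015));
  double ghk;
  const double zv = 2.0 * V / RTF;
  if (std::fabs(V) < 1e-4) {
    ghk = 0.5 * RTF * (Cai - 0.341 * Cao);
  } else {
    ghk = V * (Cai * std::exp(zv) - 0.341 * Cao) / (std::exp(zv) - 1.0);
  }
  const double ICaL = p[P_GCaL] * d * f * fca * ghk;

  // transient outward K+: instantaneous activation, gated inactivation
  const double ainf = 1.0 / (1.0 + std::exp(-(V - 5.0) / 9.0));
  const double Ito = p[P_Gto] * ainf * r * (V - EK);
  const double rinf = 1.0 / (1.0 + std::exp((V + 40.0) / 5.0));
  const double taur = 10.0 + 30.0 / (1.0 + std::exp((V + 45.0) / 8.0));

  // delayed rectifiers
  const double rkr = 1.0 / (1.0 + std::exp((V + 15.0) / 22.0));
  const double IKr = p[P_GKr] * xr * rkr * (V - EK);
  const double xrinf = 1.0 / (1.0 + std::exp(-(V + 20.0) / 7.0));
  const double tauxr = p[P_tauxr] *
      (120.0 + 300.0 / (1.0 + std::exp((V + 30.0) / 10.0)));
  const double IKs = p[P_GKs] * xs * xs * (V - EK);
  const double xsinf = 1.0 / (1.0 + std::exp(-(V - 2.0) / 14.0));
  const double tauxs = 500.0;

  // inward rectifier with sqrt(Ko) conductance dependence
  const double kinf = 1.0 / (1.0 + std::exp((V - EK - 10.0) / 11.0));
  const double IK1 = p[P_GK1] * std::sqrt(Ko / 5.4) * kinf * (V - EK);

  // Na+/K+ pump
  const double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                             0.0353 * std::exp(-V / RTF));
  const double INaK = p[P_KNaK] * fnak * (Ko / (Ko + 1.5)) /
      (1.0 + std::pow(10.0 / Nai, 1.5));

  // Na+/Ca2+ exchanger (Luo-Rudy form)
  const double e1 = std::exp(0.35 * V / RTF);
  const double e2 = std::exp(-0.65 * V / RTF);
  const double INCX = p[P_KNCX] *
      (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
      ((669921.875 + Nao * Nao * Nao) * (1.38 + Cao) * (1.0 + 0.1 * e2));

  // sarcolemmal Ca2+ pump and background currents
  const double IpCa = p[P_GpCa] * Cai / (Cai + 0.0005);
  const double IbNa = p[P_GbNa] * (V - ENa);
  const double IbCa = p[P_GbCa] * (V - ECa);

  // SR Ca2+ handling
  const double Jup = p[P_KSERCA] * Cai * Cai /
      (Cai * Cai + p[P_Kmup] * p[P_Kmup]);
  const double Jrel = p[P_KRyR] * d * fca * (CaSR - Cai);
  const double Jleak = p[P_kleak] * (CaSR - Cai);

  const double kd = p[P_Kdbuf];
  const double beta = 1.0 / (1.0 + p[P_Bmax] * kd / ((kd + Cai) * (kd + Cai)));
  const double betasr = 1.0 / (1.0 + 10.0 * 0.8 / ((0.8 + CaSR) * (0.8 + CaSR)));

  dy[0] = -(INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INCX + IpCa +
            IbNa + IbCa + istim);
  dy[1] = (hinf - h) / tauh;
  dy[2] = (dinf - d) / taud;
  dy[3] = (finf - f) / tauf;
  dy[4] = (rinf - r) / taur;
  dy[5] = (xrinf - xr) / tauxr;
  dy[6] = (xsinf - xs) / tauxs;
  dy[7] = beta * (-(ICaL + IbCa + IpCa - 2.0 * INCX) * p[P_conv] +
                  Jrel + Jleak - Jup);
  dy[8] = betasr * (Jup - Jrel - Jleak) * p[P_vsr];
}

// [[Rcpp::export]]
NumericVector cc_rhs(double t, NumericVector state, NumericVector params,
                     double istim = 0.0) {
  if (state.size() != N_STATE) stop("state must have length %d", N_STATE);
  if (params.size() != N_PAR) stop("params must have length %d", N_PAR);
  NumericVector dy(N_STATE);
  rhs(t, state.begin(), dy.begin(), params.begin(), istim);
  return dy;
}

// Dormand-Prince 5(4) with FSAL, PI-free standard controller, cubic Hermite
// dense output for (V, Cai).  The stimulus is piecewise constant; segment
// boundaries are hit exactly.
struct DP5 {
  const double* p;
  double rtol, atol;
  double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE],
         k5[N_STATE], k6[N_STATE], k7[N_STATE], ytmp[N_STATE];

  bool step(double t, double* y, double h, double istim, double* ynew,
            double* err_out) {
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                        a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                        a65 = -5103.0 / 18656;
    static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                        b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    static const double e1c = 71.0 / 57600, e3c = -71.0 / 16695,
                        e4c = 71.0 / 1920, e5c = -17253.0 / 339200,
                        e6c = 22.0 / 525, e7c = -1.0 / 40;
    int i;
    for (i = 0; i < N_STATE; i++) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(t + h / 5, ytmp, k2, p, istim);
    for (i = 0; i < N_STATE; i++)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + 3 * h / 10, ytmp, k3, p, istim);
    for (i = 0; i < N_STATE; i++)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + 4 * h / 5, ytmp, k4, p, istim);
    for (i = 0; i < N_STATE; i++)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(t + 8 * h / 9, ytmp, k5, p, istim);
    for (i = 0; i < N_STATE; i++)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, ytmp, k6, p, istim);
    for (i = 0; i < N_STATE; i++)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, ynew, k7, p, istim);
    double err = 0.0;
    for (i = 0; i < N_STATE; i++) {
      const double e = h * (e1c * k1[i] + e3c * k3[i] + e4c * k4[i] +
                            e5c * k5[i] + e6c * k6[i] + e7c * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      err += (e / sc) * (e / sc);
      if (!std::isfinite(ynew[i])) { *err_out = 1e10; return false; }
    }
    err = std::sqrt(err / N_STATE);
    *err_out = err;
    return err <= 1.0;
  }
};

// [[Rcpp::export]]
List cc_integrate(NumericVector params, NumericVector state0,
                  double duration, double stim_amp, double stim_dur,
                  double stim_period, double stim_start,
                  double record_from, double dt_out,
                  double rtol, double atol) {
  if (params.size() != N_PAR) stop("params must have length %d", N_PAR);
  if (state0.size() != N_STATE) stop("state0 must have length %d", N_STATE);

  // stimulus segment boundaries
  std::vector<double> brk;
  brk.push_back(0.0);
  if (stim_amp > 0.0 && stim_period > 0.0) {
    for (double t0 = stim_start; t0 < duration; t0 += stim_period) {
      if (t0 > 0.0) brk.push_back(t0);
      if (t0 + stim_dur < duration) brk.push_back(t0 + stim_dur);
    }
  }
  brk.push_back(duration);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());

  const int n_out = (int)std::floor((duration - record_from) / dt_out + 1e-9) + 1;
  NumericVector t_out(n_out), v_out(n_out), ca_out(n_out);
  for (int i = 0; i < n_out; i++) t_out[i] = record_from + i * dt_out;
  std::fill(v_out.begin(), v_out.end(), NA_REAL);
  std::fill(ca_out.begin(), ca_out.end(), NA_REAL);
  int i_out = 0;

  DP5 s;
  s.p = params.begin();
  s.rtol = rtol; s.atol = atol;

  double y[N_STATE], ynew[N_STATE];
  for (int i = 0; i < N_STATE; i++) y[i] = state0[i];
  double h = 0.01;
  const double hmax = 2.0, hmin = 1e-7;
  bool failed = false;
  long n_steps = 0;

  // record t = record_from if it coincides with 0
  if (i_out < n_out && t_out[i_out] <= 0.0 + 1e-12) {
    v_out[i_out] = y[0]; ca_out[i_out] = y[7]; i_out++;
  }

  for (size_t seg = 0; seg + 1 < brk.size() && !failed; seg++) {
    double t = brk[seg];
    const double t_end = brk[seg + 1];
    double istim = 0.0;
    if (stim_amp > 0.0 && stim_period > 0.0) {
      const double tt = t - stim_start + 1e-9;
      const double ph = tt - std::floor(tt / stim_period) * stim_period;
      if (t >= stim_start - 1e-9 && ph >= -1e-9 && ph < stim_dur - 1e-9)
        istim = -stim_amp;  // inward (depolarising)
    }
    rhs(t, y, s.k1, params.begin(), istim);
    while (t < t_end - 1e-9) {
      if (h > t_end - t) h = t_end - t;
      if (h > hmax) h = hmax;
      double err;
      const bool ok = s.step(t, y, h, istim, ynew, &err);
      if (ok) {
        // dense output within [t, t+h] via cubic Hermite on V and Cai
        const double t1 = t + h;
        while (i_out < n_out && t_out[i_out] <= t1 + 1e-9) {
          const double th = (t_out[i_out] - t) / h;
          const double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
          const double h10 = th * (1 - th) * (1 - th);
          const double h01 = th * th * (3 - 2 * th);
          const double h11 = th * th * (th - 1);
          v_out[i_out] = h00 * y[0] + h10 * h * s.k1[0] +
                         h01 * ynew[0] + h11 * h * s.k7[0];
          ca_out[i_out] = h00 * y[7] + h10 * h * s.k1[7] +
                          h01 * ynew[7] + h11 * h * s.k7[7];
          i_out++;
        }
        t = t1;
        for (int i = 0; i < N_STATE; i++) { y[i] = ynew[i]; s.k1[i] = s.k7[i]; }
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        if (fac > 5.0) fac = 5.0;
        h *= fac;
        if (std::fabs(y[0]) > 1000.0) { failed = true; break; }
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.2) fac = 0.2;
        if (fac > 1.0) fac = 1.0;
        h *= fac;
      }
      n_steps++;
      if (h < hmin) { failed = true; break; }
      if (n_steps > 2000000L) { failed = true; break; }
    }
  }

  NumericVector yfinal(N_STATE);
  for (int i = 0; i < N_STATE; i++) yfinal[i] = y[i];
  return List::create(_["time"] = t_out, _["V"] = v_out, _["Cai"] = ca_out,
                      _["state"] = yfinal, _["failed"] = failed,
                      _["n_steps"] = (double)n_steps);
}
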
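// Fixed-step numerical cores for the QIF E-I circuit analyses:
//  - RK4 integrator for the 8-dimensional mean-field reduction,
//  - RK4 integrator with ring-buffer delay history for the 16-dimensional
//    bidirectionally coupled reduced system,
//  - Euler integrators for the finite-size QIF spiking networks (single
//    circuit and delay-coupled pair) with exact exponential synapse decay
//    and per-spike jump updates.
// All schemes are fixed-step by design so that runs are bit-reproducible
// and the delayed lookups align with the stored history grid.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct MFParams {
  double tau_e, eta_e, delta_e;
  double tau_i, eta_i, delta_i;
  double tau_s;
  double jee, jei, jie, jii;
};

MFParams unpack_params(const NumericVector& p) {
  MFParams P;
  P.tau_e = p[0]; P.eta_e = p[1]; P.delta_e = p[2];
  P.tau_i = p[3]; P.eta_i = p[4]; P.delta_i = p[5];
  P.tau_s = p[6];
  P.jee = p[7]; P.jei = p[8]; P.jie = p[9]; P.jii = p[10];
  return P;
}

// Single-circuit field.  State ordering: r_e, V_e, s_ee, s_ei, r_i, V_i,
// s_ie, s_ii.  cross_e / cross_i are additive inputs to the s_ee and s_ie
// equations (delayed pyramidal rate from the partner circuit, or 0).
inline void mf_rhs(const double* y, double* dy, const MFParams& P,
                   double Ie_ext, double Ii_ext,
                   double cross_e = 0.0, double cross_i = 0.0) {
  const double pi = M_PI;
  const double re = y[0], Ve = y[1], see = y[2], sei = y[3];
  const double ri = y[4], Vi = y[5], sie = y[6], sii = y[7];
  const double Ie = Ie_ext + P.tau_e * see - P.tau_e * sei;
  const double Ii = Ii_ext + P.tau_i * sie - P.tau_i * sii;
  dy[0] = (P.delta_e / (pi * P.tau_e) + 2.0 * re * Ve) / P.tau_e;
  dy[1] = (Ve * Ve + P.eta_e + Ie -
           P.tau_e * P.tau_e * pi * pi * re * re) / P.tau_e;
  dy[2] = (-see + P.jee * re + cross_e) / P.tau_s;
  dy[3] = (-sei + P.jei * ri) / P.tau_s;
  dy[4] = (P.delta_i / (pi * P.tau_i) + 2.0 * ri * Vi) / P.tau_i;
  dy[5] = (Vi * Vi + P.eta_i + Ii -
           P.tau_i * P.tau_i * pi * pi * ri * ri) / P.tau_i;
  dy[6] = (-sie + P.jie * re + cross_i) / P.tau_s;
  dy[7] = (-sii + P.jii * ri) / P.tau_s;
}

// Piecewise-constant lookup: value of the segment whose start is the last
// one <= t.  Segment starts must be sorted ascending.
inline double drive_at(const NumericVector& starts, const NumericVector& vals,
                       double t) {
  const int n = starts.size();
  if (n == 1 || t <= starts[0]) return vals[0];
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (starts[mid] <= t) lo = mid; else hi = mid - 1;
  }
  return vals[lo];
}

inline bool finite8(const double* y, int n) {
  for (int k = 0; k < n; ++k)
    if (!std::isfinite(y[k]) || std::fabs(y[k]) > 1e10) return false;
  return true;
}

// 4-point Lagrange (cubic) interpolation on a uniform unit grid.
// x is the fractional coordinate, nodes b[i] exist for 0 <= i < filled.
inline double cubic_lookup(const std::vector<double>& b, double x, int filled) {
  if (x <= 0.0) return b[0];
  int i = (int)std::floor(x);
  double f = x - i;
  if (f < 1e-12) return b[i];
  int i0 = i - 1;
  if (i0 < 0) i0 = 0;
  if (i0 > filled - 4) i0 = filled - 4;
  const double u = x - i0;  // in [0, 3]
  const double y0 = b[i0], y1 = b[i0 + 1], y2 = b[i0 + 2], y3 = b[i0 + 3];
  // Lagrange basis on nodes 0,1,2,3
  const double l0 = (u - 1) * (u - 2) * (u - 3) / (-6.0);
  const double l1 = u * (u - 2) * (u - 3) / (2.0);
  const double l2 = u * (u - 1) * (u - 3) / (-2.0);
  const double l3 = u * (u - 1) * (u - 2) / (6.0);
  return y0 * l0 + y1 * l1 + y2 * l2 + y3 * l3;
}

}  // namespace

//' @name mf_integrate_cpp
//' Internal RK4 core for the 8-dimensional reduced E-I system.
// [[Rcpp::export]]
NumericMatrix mf_integrate_cpp(NumericVector y0, NumericVector par,
                               NumericVector drive_starts,
                               NumericVector drive_e, NumericVector drive_i,
                               double t0, int nsteps, double h,
                               int store_every, NumericVector pulse) {
  const MFParams P = unpack_params(par);
  // pulse = (target 0/1/2, amplitude, onset, duration)
  const int p_target = (int)pulse[0];
  const double p_amp = pulse[1], p_on = pulse[2], p_dur = pulse[3];

  const int nstore = nsteps / store_every + 1;
  NumericMatrix out(nstore, 9);
  double y[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int k = 0; k < 8; ++k) y[k] = y0[k];

  auto I_of = [&](double t, int pop) {
    double I = (pop == 1) ? drive_at(drive_starts, drive_e, t)
                          : drive_at(drive_starts, drive_i, t);
    if (p_target == pop && t >= p_on && t < p_on + p_dur) I += p_amp;
    return I;
  };

  int row = 0;
  out(row, 0) = t0;
  for (int k = 0; k < 8; ++k) out(row, k + 1) = y[k];
  ++row;

  for (int n = 0; n < nsteps; ++n) {
    const double t = t0 + n * h;
    const double th = t + 0.5 * h, t1 = t + h;
    mf_rhs(y, k1, P, I_of(t, 1), I_of(t, 2));
    for (int k = 0; k < 8; ++k) tmp[k] = y[k] + 0.5 * h * k1[k];
    mf_rhs(tmp, k2, P, I_of(th, 1), I_of(th, 2));
    for (int k = 0; k < 8; ++k) tmp[k] = y[k] + 0.5 * h * k2[k];
    mf_rhs(tmp, k3, P, I_of(th, 1), I_of(th, 2));
    for (int k = 0; k < 8; ++k) tmp[k] = y[k] + h * k3[k];
    mf_rhs(tmp, k4, P, I_of(t1, 1), I_of(t1, 2));
    for (int k = 0; k < 8; ++k)
      y[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (!finite8(y, 8))
      stop("non-finite mean-field state at t = %f", t1);
    if ((n + 1) % store_every == 0) {
      out(row, 0) = t1;
      for (int k = 0; k < 8; ++k) out(row, k + 1) = y[k];
      ++row;
    }
  }
  return out;
}

//' @name dde_integrate_cpp
//' Internal RK4 core for the 16-dimensional delay-coupled reduced system.
//' History buffers hold the pyramidal rate of each circuit on the step grid
//' covering [t0 - d, t0]; delayed stage values are cubic-interpolated.
// [[Rcpp::export]]
NumericMatrix dde_integrate_cpp(NumericVector y0, NumericVector par,
                                double Ie_ext, double Ii_ext,
                                double gee, double gie, int nd,
                                NumericVector hist1, NumericVector hist2,
                                double t0, int nsteps, double h,
                                int store_every, NumericVector pulse) {
  const MFParams P = unpack_params(par);
  // pulse = (circuit 0/1/2, population 1(E)/2(I), amplitude, onset, duration)
  const int p_circ = (int)pulse[0], p_pop = (int)pulse[1];
  const double p_amp = pulse[2], p_on = pulse[3], p_dur = pulse[4];

  if (nd > 0 && (hist1.size() != nd + 1 || hist2.size() != nd + 1))
    stop("history length must equal nd + 1");
  if (nd == 1)
    stop("delay must be zero or at least two integration steps");

  std::vector<double> b1(nd + 1 + nsteps), b2(nd + 1 + nsteps);
  for (int k = 0; k <= nd && nd > 0; ++k) { b1[k] = hist1[k]; b2[k] = hist2[k]; }
  if (nd == 0) { b1[0] = y0[0]; b2[0] = y0[8]; }

  const int nstore = nsteps / store_every + 1;
  NumericMatrix out(nstore, 17);
  double y[16], k1[16], k2[16], k3[16], k4[16], tmp[16];
  for (int k = 0; k < 16; ++k) y[k] = y0[k];

  // stage RHS at stage time ts with stage state z; buffer coordinate of the
  // delayed time ts - d is (ts - t0)/h when nd > 0.
  auto rhs16 = [&](const double* z, double* dz, double ts, int filled) {
    double re2_del, re1_del;
    if (nd == 0) { re2_del = z[8]; re1_del = z[0]; }
    else {
      const double x = (ts - t0) / h;
      re2_del = cubic_lookup(b2, x, filled);
      re1_del = cubic_lookup(b1, x, filled);
    }
    double Ie1 = Ie_ext, Ii1 = Ii_ext, Ie2 = Ie_ext, Ii2 = Ii_ext;
    if (p_circ > 0 && ts >= p_on && ts < p_on + p_dur) {
      if (p_circ == 1) { if (p_pop == 1) Ie1 += p_amp; else Ii1 += p_amp; }
      else             { if (p_pop == 1) Ie2 += p_amp; else Ii2 += p_amp; }
    }
    mf_rhs(z, dz, P, Ie1, Ii1, gee * re2_del, gie * re2_del);
    mf_rhs(z + 8, dz + 8, P, Ie2, Ii2, gee * re1_del, gie * re1_del);
  };

  int row = 0;
  out(row, 0) = t0;
  for (int k = 0; k < 16; ++k) out(row, k + 1) = y[k];
  ++row;

  for (int n = 0; n < nsteps; ++n) {
    const double t = t0 + n * h;
    const int filled = nd + n + 1;  // buffer entries known so far
    rhs16(y, k1, t, filled);
    for (int k = 0; k < 16; ++k) tmp[k] = y[k] + 0.5 * h * k1[k];
    rhs16(tmp, k2, t + 0.5 * h, filled);
    for (int k = 0; k < 16; ++k) tmp[k] = y[k] + 0.5 * h * k2[k];
    rhs16(tmp, k3, t + 0.5 * h, filled);
    for (int k = 0; k < 16; ++k) tmp[k] = y[k] + h * k3[k];
    rhs16(tmp, k4, t + h, filled);
    for (int k = 0; k < 16; ++k)
      y[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (!finite8(y, 16))
      stop("non-finite coupled state at t = %f", t + h);
    if (nd > 0) { b1[nd + n + 1] = y[0]; b2[nd + n + 1] = y[8]; }
    if ((n + 1) % store_every == 0) {
      out(row, 0) = t + h;
      for (int k = 0; k < 16; ++k) out(row, k + 1) = y[k];
      ++row;
    }
  }

  // Tail of the rate history, so runs can be chained.
  const int tail_len = nd + 1;
  NumericVector tail1(tail_len), tail2(tail_len);
  if (nd > 0) {
    for (int k = 0; k < tail_len; ++k) {
      tail1[k] = b1[nsteps + k];
      tail2[k] = b2[nsteps + k];
    }
  } else { tail1[0] = y[0]; tail2[0] = y[8]; }
  out.attr("re1_tail") = tail1;
  out.attr("re2_tail") = tail2;
  return out;
}

//' @name spiking_net_cpp
//' Internal Euler core for one finite-size QIF E-I network.
// [[Rcpp::export]]
List spiking_net_cpp(NumericVector eta_e, NumericVector eta_i,
                     NumericVector v0e, NumericVector v0i,
                     NumericVector par, NumericVector Ie_steps,
                     NumericVector Ii_steps, double h, NumericVector s0,
                     double v_th, double v_r, int n_ref_e, int n_ref_i) {
  const MFParams P = unpack_params(par);
  const int Ne = eta_e.size(), Ni = eta_i.size();
  const int nsteps = Ie_steps.size();
  const double dec = std::exp(-h / P.tau_s);

  std::vector<double> ve(v0e.begin(), v0e.end()), vi(v0i.begin(), v0i.end());
  std::vector<int> refe(Ne, 0), refi(Ni, 0);
  double see = s0[0], sei = s0[1], sie = s0[2], sii = s0[3];

  std::vector<double> te, ti;
  std::vector<int> ide, idi;
  te.reserve(1 << 16); ti.reserve(1 << 16);
  ide.reserve(1 << 16); idi.reserve(1 << 16);
  IntegerVector cnt_e(nsteps), cnt_i(nsteps);

  for (int n = 0; n < nsteps; ++n) {
    const double t1 = (n + 1) * h;
    const double Ie = Ie_steps[n] + P.tau_e * (see - sei);
    const double Ii = Ii_steps[n] + P.tau_i * (sie - sii);
    int ce = 0, ci = 0;
    const double ae = h / P.tau_e, ai = h / P.tau_i;
    for (int j = 0; j < Ne; ++j) {
      if (refe[j] > 0) { --refe[j]; continue; }
      double v = ve[j];
      v += ae * (eta_e[j] + v * v + Ie);
      if (v >= v_th) {
        v = v_r; ++ce; te.push_back(t1); ide.push_back(j + 1);
        refe[j] = n_ref_e;
      }
      ve[j] = v;
    }
    for (int j = 0; j < Ni; ++j) {
      if (refi[j] > 0) { --refi[j]; continue; }
      double v = vi[j];
      v += ai * (eta_i[j] + v * v + Ii);
      if (v >= v_th) {
        v = v_r; ++ci; ti.push_back(t1); idi.push_back(j + 1);
        refi[j] = n_ref_i;
      }
      vi[j] = v;
    }
    see = see * dec + P.jee * ce / (Ne * P.tau_s);
    sei = sei * dec + P.jei * ci / (Ni * P.tau_s);
    sie = sie * dec + P.jie * ce / (Ne * P.tau_s);
    sii = sii * dec + P.jii * ci / (Ni * P.tau_s);
    if (!std::isfinite(see + sei + sie + sii))
      stop("non-finite synaptic state at t = %f", t1);
    cnt_e[n] = ce; cnt_i[n] = ci;
  }

  return List::create(
      _["t_e"] = NumericVector(te.begin(), te.end()),
      _["id_e"] = IntegerVector(ide.begin(), ide.end()),
      _["t_i"] = NumericVector(ti.begin(), ti.end()),
      _["id_i"] = IntegerVector(idi.begin(), idi.end()),
      _["counts_e"] = cnt_e, _["counts_i"] = cnt_i,
      _["s_final"] = NumericVector::create(see, sei, sie, sii),
      _["v_final_e"] = NumericVector(ve.begin(), ve.end()),
      _["v_final_i"] = NumericVector(vi.begin(), vi.end()));
}

//' @name coupled_spiking_cpp
//' Internal Euler core for two delay-coupled QIF E-I networks.  Cross
//' projections originate from the pyramidal cells only; a ring of per-step
//' E-spike counts carries the in-flight delayed spikes.
// [[Rcpp::export]]
List coupled_spiking_cpp(NumericVector eta_e1, NumericVector eta_i1,
                         NumericVector eta_e2, NumericVector eta_i2,
                         NumericVector v0e1, NumericVector v0i1,
                         NumericVector v0e2, NumericVector v0i2,
                         NumericVector par, double Ie_ext, double Ii_ext,
                         double gee, double gie, int nd,
                         double h, int nsteps, double v_th, double v_r,
                         NumericVector s01, NumericVector s02, int n_ref_e, int n_ref_i) {
  const MFParams P = unpack_params(par);
  const int Ne = eta_e1.size(), Ni = eta_i1.size();
  const double dec = std::exp(-h / P.tau_s);

  std::vector<double> ve1(v0e1.begin(), v0e1.end()), vi1(v0i1.begin(), v0i1.end());
  std::vector<double> ve2(v0e2.begin(), v0e2.end()), vi2(v0i2.begin(), v0i2.end());
  std::vector<int> re1(Ne, 0), ri1(Ni, 0), re2(Ne, 0), ri2(Ni, 0);
  double s1[4], s2[4];  // see, sei, sie, sii
  for (int k = 0; k < 4; ++k) { s1[k] = s01[k]; s2[k] = s02[k]; }

  std::vector<int> ce_hist(nsteps, 0), ce2_hist(nsteps, 0);
  std::vector<double> te1, ti1, te2, ti2;
  std::vector<int> ide1, idi1, ide2, idi2;
  IntegerVector cnt_e1(nsteps), cnt_i1(nsteps), cnt_e2(nsteps), cnt_i2(nsteps);

  for (int n = 0; n < nsteps; ++n) {
    const double t1 = (n + 1) * h;
    const double Ie1 = Ie_ext + P.tau_e * (s1[0] - s1[1]);
    const double Ii1 = Ii_ext + P.tau_i * (s1[2] - s1[3]);
    const double Ie2 = Ie_ext + P.tau_e * (s2[0] - s2[1]);
    const double Ii2 = Ii_ext + P.tau_i * (s2[2] - s2[3]);
    const double ae = h / P.tau_e, ai = h / P.tau_i;
    int ce1 = 0, ci1 = 0, ce2 = 0, ci2 = 0;
    for (int j = 0; j < Ne; ++j) {
      if (re1[j] > 0) { --re1[j]; } else {
        double v = ve1[j];
        v += ae * (eta_e1[j] + v * v + Ie1);
        if (v >= v_th) { v = v_r; ++ce1; te1.push_back(t1); ide1.push_back(j + 1); re1[j] = n_ref_e; }
        ve1[j] = v;
      }
      if (re2[j] > 0) { --re2[j]; } else {
        double v = ve2[j];
        v += ae * (eta_e2[j] + v * v + Ie2);
        if (v >= v_th) { v = v_r; ++ce2; te2.push_back(t1); ide2.push_back(j + 1); re2[j] = n_ref_e; }
        ve2[j] = v;
      }
    }
    for (int j = 0; j < Ni; ++j) {
      if (ri1[j] > 0) { --ri1[j]; } else {
        double v = vi1[j];
        v += ai * (eta_i1[j] + v * v + Ii1);
        if (v >= v_th) { v = v_r; ++ci1; ti1.push_back(t1); idi1.push_back(j + 1); ri1[j] = n_ref_i; }
        vi1[j] = v;
      }
      if (ri2[j] > 0) { --ri2[j]; } else {
        double v = vi2[j];
        v += ai * (eta_i2[j] + v * v + Ii2);
        if (v >= v_th) { v = v_r; ++ci2; ti2.push_back(t1); idi2.push_back(j + 1); ri2[j] = n_ref_i; }
        vi2[j] = v;
      }
    }
    ce_hist[n] = ce1; ce2_hist[n] = ce2;
    // delayed cross spike counts (silent history before the run starts)
    const int m = n - nd;
    const int dce1 = (m >= 0) ? ce_hist[m] : 0;
    const int dce2 = (m >= 0) ? ce2_hist[m] : 0;
    s1[0] = s1[0] * dec + (P.jee * ce1 + gee * dce2) / (Ne * P.tau_s);
    s1[1] = s1[1] * dec + P.jei * ci1 / (Ni * P.tau_s);
    s1[2] = s1[2] * dec + (P.jie * ce1 + gie * dce2) / (Ne * P.tau_s);
    s1[3] = s1[3] * dec + P.jii * ci1 / (Ni * P.tau_s);
    s2[0] = s2[0] * dec + (P.jee * ce2 + gee * dce1) / (Ne * P.tau_s);
    s2[1] = s2[1] * dec + P.jei * ci2 / (Ni * P.tau_s);
    s2[2] = s2[2] * dec + (P.jie * ce2 + gie * dce1) / (Ne * P.tau_s);
    s2[3] = s2[3] * dec + P.jii * ci2 / (Ni * P.tau_s);
    if (!std::isfinite(s1[0] + s1[1] + s1[2] + s1[3] +
                       s2[0] + s2[1] + s2[2] + s2[3]))
      stop("non-finite synaptic state at t = %f", t1);
    cnt_e1[n] = ce1; cnt_i1[n] = ci1; cnt_e2[n] = ce2; cnt_i2[n] = ci2;
  }

  return List::create(
      _["t_e1"] = NumericVector(te1.begin(), te1.end()),
      _["id_e1"] = IntegerVector(ide1.begin(), ide1.end()),
      _["t_i1"] = NumericVector(ti1.begin(), ti1.end()),
      _["id_i1"] = IntegerVector(idi1.begin(), idi1.end()),
      _["t_e2"] = NumericVector(te2.begin(), te2.end()),
      _["id_e2"] = IntegerVector(ide2.begin(), ide2.end()),
      _["t_i2"] = NumericVector(ti2.begin(), ti2.end()),
      _["id_i2"] = IntegerVector(idi2.begin(), idi2.end()),
      _["counts_e1"] = cnt_e1, _["counts_i1"] = cnt_i1,
      _["counts_e2"] = cnt_e2, _["counts_i2"] = cnt_i2);
}

//' @name adjoint_backward_cpp
//' Internal backward RK4 sweep for the adjoint (iPRC) equation
//' -dZ/dt = M(t)^T Z along a sampled limit cycle.  The cycle enters through
//' the four state samples needed by M(t): r_e, V_e, r_i, V_i, given on a
//' uniform grid of M points over one period and interpolated circularly
//' (cubic).  Returns Z at the grid points after convergence.
// [[Rcpp::export]]
List adjoint_backward_cpp(NumericMatrix cyc, NumericVector par, double T,
                          double tol, int max_periods) {
  const MFParams P = unpack_params(par);
  const int M = cyc.nrow();
  const double h = T / M;

  // periodic cubic lookup of cycle column c at grid coordinate x (in samples)
  auto cyc_at = [&](int c, double x) {
    x -= M * std::floor(x / M);  // wrap to [0, M)
    if (x >= M) x -= M;
    int i = (int)std::floor(x);
    double u = x - i;
    if (u < 1e-12) return cyc(i % M, c);
    int im = (i - 1 + M) % M, i1 = (i + 1) % M, i2 = (i + 2) % M;
    const double y0 = cyc(im, c), y1 = cyc(i, c), y2 = cyc(i1, c), y3 = cyc(i2, c);
    const double v = u + 1.0;
    const double l0 = (v - 1) * (v - 2) * (v - 3) / (-6.0);
    const double l1 = v * (v - 2) * (v - 3) / (2.0);
    const double l2 = v * (v - 1) * (v - 3) / (-2.0);
    const double l3 = v * (v - 1) * (v - 2) / (6.0);
    return y0 * l0 + y1 * l1 + y2 * l2 + y3 * l3;
  };

  // dZ/dt = -M(t)^T Z written out; x is the grid coordinate t/h.
  auto rhs = [&](const double* z, double* dz, double x) {
    const double re = cyc_at(0, x), Ve = cyc_at(1, x);
    const double ri = cyc_at(2, x), Vi = cyc_at(3, x);
    const double pi = M_PI;
    // Jacobian rows of the single-circuit field (see mf_rhs)
    // dz_k = -sum_j M(j,k) z_j
    dz[0] = -(2.0 * Ve / P.tau_e * z[0] +
              (-2.0 * P.tau_e * pi * pi * re) * z[1] +
              P.jee / P.tau_s * z[2] + P.jie / P.tau_s * z[6]);
    dz[1] = -(2.0 * re / P.tau_e * z[0] + 2.0 * Ve / P.tau_e * z[1]);
    dz[2] = -(z[1] * 1.0 + (-1.0 / P.tau_s) * z[2]);
    dz[3] = -(z[1] * (-1.0) + (-1.0 / P.tau_s) * z[3]);
    dz[4] = -(2.0 * Vi / P.tau_i * z[4] +
              (-2.0 * P.tau_i * pi * pi * ri) * z[5] +
              P.jei / P.tau_s * z[3] + P.jii / P.tau_s * z[7]);
    dz[5] = -(2.0 * ri / P.tau_i * z[4] + 2.0 * Vi / P.tau_i * z[5]);
    dz[6] = -(z[5] * 1.0 + (-1.0 / P.tau_s) * z[6]);
    dz[7] = -(z[5] * (-1.0) + (-1.0 / P.tau_s) * z[7]);
  };

  double z[8], zp[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int k = 0; k < 8; ++k) z[k] = 1.0 / std::sqrt(8.0);

  auto backward_period = [&](NumericMatrix* store) {
    // integrate from x = M down to x = 0 in M steps of -h
    if (store) for (int k = 0; k < 8; ++k) (*store)(0, k) = z[k];
    for (int n = M; n > 0; --n) {
      const double x = (double)n;
      rhs(z, k1, x);
      for (int k = 0; k < 8; ++k) tmp[k] = z[k] - 0.5 * h * k1[k];
      rhs(tmp, k2, x - 0.5);
      for (int k = 0; k < 8; ++k) tmp[k] = z[k] - 0.5 * h * k2[k];
      rhs(tmp, k3, x - 0.5);
      for (int k = 0; k < 8; ++k) tmp[k] = z[k] - h * k3[k];
      rhs(tmp, k4, x - 1.0);
      for (int k = 0; k < 8; ++k)
        z[k] -= h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
      if (store && n > 1) for (int k = 0; k < 8; ++k) (*store)(n - 1, k) = z[k];
    }
  };

  int period = 0;
  double rel = R_PosInf;
  for (; period < max_periods; ++period) {
    for (int k = 0; k < 8; ++k) zp[k] = z[k];
    backward_period(nullptr);
    double nrm = 0.0, diff = 0.0;
    for (int k = 0; k < 8; ++k) nrm += z[k] * z[k];
    nrm = std::sqrt(nrm);
    if (!std::isfinite(nrm) || nrm == 0.0)
      stop("adjoint iteration lost the solution (period %d)", period + 1);
    for (int k = 0; k < 8; ++k) z[k] /= nrm;
    for (int k = 0; k < 8; ++k) {
      const double d2 = z[k] - zp[k];
      diff += d2 * d2;
    }
    rel = std::sqrt(diff);
    if (rel < tol) break;
  }
  if (rel >= tol)
    stop("adjoint iteration did not converge within %d periods", max_periods);

  NumericMatrix Z(M, 8);
  backward_period(&Z);
  NumericVector zfinal(8);
  for (int k = 0; k < 8; ++k) zfinal[k] = z[k];
  return List::create(_["Z"] = Z, _["z_final"] = zfinal,
                      _["periods"] = period + 1, _["rel_change"] = rel);
}
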
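// Single-compartment Hodgkin-Huxley integrator.
//
// Scheme: exponential update of gating variables at frozen voltage within a
// step, then an implicit (backward Euler) linear update of the membrane
// potential. Unconditionally stable, which matters because Na+ activation is
// stiff relative to the 0.025-ms default step.
//
// Units throughout: mV, ms, pA, pF, nS (1 nS * 1 mV = 1 pA).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TAU_FLOOR = 1e-4; // ms; guards exp overflow, never hit at physiological V

struct Gate {
  int kind;           // 0 activation, 1 inactivation
  double vhalf, q;    // Boltzmann midpoint and slope (q > 0)
  int form;           // 0 = bell4 (a, ka, b, kb); 1 = bell6 (+ taumin, tauscale)
  double a, ka, b, kb, taumin, tauscale;

  double ss(double V) const {
    double z = (kind == 0) ? (vhalf - V) / q : (V - vhalf) / q;
    return 1.0 / (1.0 + std::exp(z));
  }
  double tau(double V) const {
    double alpha = a * std::exp(V / ka);
    double beta  = b * std::exp(-V / kb);
    double t;
    if (form == 0) t = 1.0 / (alpha + beta);
    else           t = taumin + tauscale / (alpha + beta);
    return t > TAU_FLOOR ? t : TAU_FLOOR;
  }
};

static Gate parse_gate(const NumericVector& g) {
  Gate out;
  out.kind  = (int)g[0];
  out.vhalf = g[1];
  out.q     = g[2];
  out.form  = (int)g[3];
  out.a  = g[4]; out.ka = g[5];
  out.b  = g[6]; out.kb = g[7];
  if (out.form == 1) { out.taumin = g[8]; out.tauscale = g[9]; }
  else               { out.taumin = 0.0;  out.tauscale = 1.0; }
  return out;
}

struct NaChan {
  double g_ns; int p;
  Gate m, h;
  double xm, xh; // state
};

struct KChan {
  double g_ns;
  Gate m, h1;                 // h2 shares h1's steady-state Boltzmann
  double frac_inact, frac_h2;
  double tau_inact, tau_rec;  // two-regime h2 time constants
  double xm, xh1, xh2;
};

struct Patch {
  double c_pf, gleak_ns, eleak, ena, ek;
  std::vector<NaChan> na;
  std::vector<KChan> k;

  void init_gates(double V) {
    for (auto& c : na) { c.xm = c.m.ss(V); c.xh = c.h.ss(V); }
    for (auto& c : k)  { c.xm = c.m.ss(V); c.xh1 = c.h1.ss(V); c.xh2 = c.h1.ss(V); }
  }
  static double relax(double x, double xinf, double tau, double dt) {
    double xn = xinf + (x - xinf) * std::exp(-dt / tau);
    if (xn < 0.0) xn = 0.0;
    if (xn > 1.0) xn = 1.0;
    return xn;
  }
  void step_gates(double V, double dt) {
    for (auto& c : na) {
      c.xm = relax(c.xm, c.m.ss(V), c.m.tau(V), dt);
      c.xh = relax(c.xh, c.h.ss(V), c.h.tau(V), dt);
    }
    for (auto& c : k) {
      c.xm  = relax(c.xm,  c.m.ss(V),  c.m.tau(V),  dt);
      c.xh1 = relax(c.xh1, c.h1.ss(V), c.h1.tau(V), dt);
      double hinf = c.h1.ss(V);
      double t2 = (c.xh2 > hinf) ? c.tau_inact : c.tau_rec;
      c.xh2 = relax(c.xh2, hinf, t2, dt);
    }
  }
  // open conductances (nS)
  double gna_open() const {
    double g = 0.0;
    for (const auto& c : na) {
      double mp = 1.0;
      for (int i = 0; i < c.p; ++i) mp *= c.xm;
      g += c.g_ns * mp * c.xh;
    }
    return g;
  }
  double gk_open() const {
    double g = 0.0;
    for (const auto& c : k) {
      double m2 = c.xm * c.xm;
      double inact = c.frac_inact * ((1.0 - c.frac_h2) * c.xh1 + c.frac_h2 * c.xh2)
                   + (1.0 - c.frac_inact);
      g += c.g_ns * m2 * inact;
    }
    return g;
  }
  int n_gates() const { return 2 * (int)na.size() + 3 * (int)k.size(); }
  void record_row(NumericMatrix& M, int row) const {
    int j = 0;
    for (const auto& c : na) { M(row, j++) = c.xm; M(row, j++) = c.xh; }
    for (const auto& c : k)  { M(row, j++) = c.xm; M(row, j++) = c.xh1; M(row, j++) = c.xh2; }
  }
};

static Patch parse_patch(const List& model) {
  Patch p;
  p.c_pf     = as<double>(model["c_pf"]);
  p.gleak_ns = as<double>(model["gleak_ns"]);
  p.eleak    = as<double>(model["eleak"]);
  p.ena      = as<double>(model["ena"]);
  p.ek       = as<double>(model["ek"]);
  List na = model["na"];
  for (int i = 0; i < na.size(); ++i) {
    List ch = na[i];
    NaChan c;
    c.g_ns = as<double>(ch["g_ns"]);
    c.p    = as<int>(ch["p"]);
    c.m = parse_gate(ch["m"]);
    c.h = parse_gate(ch["h"]);
    if (c.g_ns > 0) p.na.push_back(c);
  }
  List k = model["k"];
  for (int i = 0; i < k.size(); ++i) {
    List ch = k[i];
    KChan c;
    c.g_ns = as<double>(ch["g_ns"]);
    c.m  = parse_gate(ch["m"]);
    c.h1 = parse_gate(ch["h1"]);
    c.frac_inact = as<double>(ch["frac_inact"]);
    c.frac_h2    = as<double>(ch["frac_h2"]);
    c.tau_inact  = as<double>(ch["tau_inact"]);
    c.tau_rec    = as<double>(ch["tau_rec"]);
    if (c.g_ns > 0) p.k.push_back(c);
  }
  return p;
}

// [[Rcpp::export(name = ".cc_core")]]
List cc_core(List model, NumericVector istim, double dt, double v0,
             int record_stride) {
  Patch p = parse_patch(model);
  p.init_gates(v0);
  int n = istim.size();
  NumericVector v(n);
  int nrec = (record_stride > 0) ? (n + record_stride - 1) / record_stride : 0;
  NumericMatrix gates(nrec, record_stride > 0 ? p.n_gates() : 0);

  double V = v0;
  double cdt = p.c_pf / dt;
  for (int i = 0; i < n; ++i) {
    p.step_gates(V, dt);
    double gna = p.gna_open(), gk = p.gk_open();
    double gsum = gna + gk + p.gleak_ns;
    double gE = gna * p.ena + gk * p.ek + p.gleak_ns * p.eleak;
    V = (cdt * V + gE + istim[i]) / (cdt + gsum);
    v[i] = V;
    if (record_stride > 0 && i % record_stride == 0)
      p.record_row(gates, i / record_stride);
  }
  List out = List::create(_["v"] = v);
  if (record_stride > 0) out["gates"] = gates;
  return out;
}

// [[Rcpp::export(name = ".vc_core")]]
List vc_core(List model, NumericVector vcmd, double dt, int record_stride) {
  Patch p = parse_patch(model);
  int n = vcmd.size();
  p.init_gates(vcmd[0]);
  NumericVector ina(n), ik(n), ileak(n), icap(n);
  int nrec = (record_stride > 0) ? (n + record_stride - 1) / record_stride : 0;
  NumericMatrix gates(nrec, record_stride > 0 ? p.n_gates() : 0);

  for (int i = 0; i < n; ++i) {
    double V = vcmd[i];
    p.step_gates(V, dt);
    ina[i]   = p.gna_open() * (V - p.ena);
    ik[i]    = p.gk_open()  * (V - p.ek);
    ileak[i] = p.gleak_ns * (V - p.eleak);
    icap[i]  = (i > 0) ? p.c_pf * (vcmd[i] - vcmd[i - 1]) / dt : 0.0;
    if (record_stride > 0 && i % record_stride == 0)
      p.record_row(gates, i / record_stride);
  }
  List out = List::create(_["ina"] = ina, _["ik"] = ik,
                          _["ileak"] = ileak, _["icap"] = icap);
  if (record_stride > 0) out["gates"] = gates;
  return out;
}
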
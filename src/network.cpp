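#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Double-Hill normalized activation, peak value 1 at x = 1 (x = t / t_maxE).
static inline double hill_raw(double x) {
  if (x <= 0.0) return 0.0;
  double a = std::pow(x / 0.7, 1.9);
  double b = std::pow(x / 1.17, 21.9);
  return (a / (1.0 + a)) / (1.0 + b);
}

// [[Rcpp::export(name = ".hill_activation")]]
NumericVector hill_activation(NumericVector x) {
  double h1 = hill_raw(1.0);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = hill_raw(x[i]) / h1;
  return out;
}

struct Net {
  int nn, nb, nt;
  const double *C;            // node compliances, mL/mmHg
  const double *Rw;           // Voigt wall-viscosity resistance per node
  const int *bf, *bt;         // branch from/to node (0-based)
  const double *bR, *bL;      // branch resistance / inertance
  const int *tn;              // terminal attachment node
  const double *tZ, *tR, *tC; // terminal proximal R, distal R, compliance
  const int *node_term;       // terminal index per node, -1 if none
  double Pv;                  // venous pressure
  double Ees, Eed, Pfill, Vd, Rven, Rav, Lav;
  int root;
};

// Luminal node pressures with the Voigt wall: P_n = Pc_n + Rw_n * I_c,n
// where I_c,n is the net current into the node capacitor. Branch flows
// and the valve flow are states, so the only implicit term is the
// terminal outflow (P_n - Pt)/Z, solved per node in closed form.
static void node_pressures(const Net &net, const std::vector<double> &y,
                           std::vector<double> &netq, std::vector<double> &P) {
  const int nn = net.nn, nb = net.nb;
  const double *Pc = y.data();
  const double *Q = y.data() + nn;
  const double *Pt = y.data() + nn + nb;
  double Qav = y[nn + nb + net.nt];
  std::fill(netq.begin(), netq.end(), 0.0);
  netq[net.root] += Qav;
  for (int b = 0; b < nb; ++b) {
    netq[net.bf[b]] -= Q[b];
    netq[net.bt[b]] += Q[b];
  }
  for (int n = 0; n < nn; ++n) {
    int k = net.node_term[n];
    if (k < 0) {
      P[n] = Pc[n] + net.Rw[n] * netq[n];
    } else {
      P[n] = (Pc[n] + net.Rw[n] * (netq[n] + Pt[k] / net.tZ[k])) /
             (1.0 + net.Rw[n] / net.tZ[k]);
    }
  }
}

// State layout: [Pc(nn) | Q(nb) | Pt(nt) | Qav(1) | V(1)]
// Pc are capacitor (wall-strain) pressures; luminal pressures follow
// from node_pressures(). The aortic valve is a diode with series
// resistance and inertance: the valve flow is a state, clamped to zero
// (closed) whenever it integrates below zero, re-opening when
// ventricular pressure exceeds root pressure.
static void deriv(const Net &net, const std::vector<double> &y, double E,
                  std::vector<double> &dy,
                  std::vector<double> &netq, std::vector<double> &P) {
  const int nn = net.nn, nb = net.nb, nt = net.nt;
  const double *Q = y.data() + nn;
  const double *Pt = y.data() + nn + nb;
  double Qav = y[nn + nb + nt];
  double V = y[nn + nb + nt + 1];

  node_pressures(net, y, netq, P);

  double Plv = E * (V - net.Vd);
  double dP = Plv - P[net.root];
  double Qmv = (net.Pfill > Plv) ? (net.Pfill - Plv) / net.Rven : 0.0;

  // valve open if carrying forward flow or forward pressure gradient
  dy[nn + nb + nt] = (Qav > 0.0 || dP > 0.0)
                       ? (dP - net.Rav * Qav) / net.Lav : 0.0;

  for (int b = 0; b < nb; ++b)
    dy[nn + b] = (P[net.bf[b]] - P[net.bt[b]] - net.bR[b] * Q[b]) / net.bL[b];
  for (int n = 0; n < nn; ++n) dy[n] = netq[n] / net.C[n];
  for (int k = 0; k < nt; ++k) {
    double qin = (P[net.tn[k]] - Pt[k]) / net.tZ[k];
    dy[net.tn[k]] -= qin / net.C[net.tn[k]];
    dy[nn + nb + k] = (qin - (Pt[k] - net.Pv) / net.tR[k]) / net.tC[k];
  }
  dy[nn + nb + nt + 1] = Qmv - Qav;
}

// Fixed-step RK4 integration of the lumped arterial network coupled to a
// time-varying-elastance ventricle. Runs cycle by cycle until the recorded
// node pressures repeat within `tol` (max abs difference) or `max_cycles`.
// Returns the final cycle sampled every `out_every` steps.
// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(NumericVector node_C, NumericVector node_Rw,
                          IntegerVector br_from, IntegerVector br_to,
                          NumericVector br_R, NumericVector br_L,
                          IntegerVector term_node, NumericVector term_Z,
                          NumericVector term_R, NumericVector term_C,
                          double venous_pressure,
                          double E_es, double E_ed, double filling_pressure,
                          double t_maxE, double heart_rate, double V_d,
                          double R_ven, double R_av, double L_av,
                          int root_node,
                          double dt_max, double out_dt,
                          int max_cycles, double tol, int min_cycles,
                          IntegerVector record_nodes,
                          IntegerVector record_branches,
                          double P_init) {
  Net net;
  net.nn = node_C.size(); net.nb = br_from.size(); net.nt = term_node.size();
  net.C = node_C.begin(); net.Rw = node_Rw.begin();
  std::vector<int> node_term(net.nn, -1);
  for (int k = 0; k < net.nt; ++k) node_term[term_node[k]] = k;
  net.node_term = node_term.data();
  net.bf = br_from.begin(); net.bt = br_to.begin();
  net.bR = br_R.begin(); net.bL = br_L.begin();
  net.tn = term_node.begin(); net.tZ = term_Z.begin();
  net.tR = term_R.begin(); net.tC = term_C.begin();
  net.Pv = venous_pressure;
  net.Ees = E_es; net.Eed = E_ed; net.Pfill = filling_pressure;
  net.Vd = V_d; net.Rven = R_ven; net.Rav = R_av; net.Lav = L_av;
  net.root = root_node;

  const double T = 60.0 / heart_rate;
  const int steps = (int)std::ceil(T / dt_max);
  const double dt = T / steps;
  const int out_every = std::max(1, (int)std::lround(out_dt / dt));
  const int n_out = (steps + out_every - 1) / out_every;

  // Elastance precomputed at half-step resolution over one cycle.
  std::vector<double> Etab(2 * steps + 1);
  const double h1 = hill_raw(1.0);
  for (int i = 0; i <= 2 * steps; ++i) {
    double t = 0.5 * dt * i;
    Etab[i] = E_ed + (E_es - E_ed) * hill_raw(t / t_maxE) / h1;
  }

  const int ns = net.nn + net.nb + net.nt + 2;
  std::vector<double> y(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), ytmp(ns);
  std::vector<double> netq(net.nn), Pnode(net.nn);
  for (int n = 0; n < net.nn; ++n) y[n] = P_init;
  for (int k = 0; k < net.nt; ++k) y[net.nn + net.nb + k] = P_init;
  y[ns - 1] = V_d + filling_pressure / E_ed; // start at passive filling volume

  const int nrp = record_nodes.size(), nrq = record_branches.size();
  NumericMatrix Pout(n_out, nrp), Qout(n_out, nrq);
  NumericVector qav(n_out), plv(n_out), vlv(n_out), tout(n_out);
  NumericMatrix Pprev(n_out, nrp);
  bool have_prev = false, converged = false, blew_up = false;
  double max_diff = NA_REAL;
  int cycles_run = 0;

  for (int cyc = 0; cyc < max_cycles && !converged && !blew_up; ++cyc) {
    cycles_run = cyc + 1;
    int irec = 0;
    for (int s = 0; s < steps; ++s) {
      deriv(net, y, Etab[2 * s], k1, netq, Pnode);
      if (s % out_every == 0 && irec < n_out) {
        tout[irec] = s * dt;
        for (int j = 0; j < nrp; ++j) Pout(irec, j) = Pnode[record_nodes[j]];
        for (int j = 0; j < nrq; ++j) Qout(irec, j) = y[net.nn + record_branches[j]];
        qav[irec] = y[ns - 2];
        plv[irec] = Etab[2 * s] * (y[ns - 1] - V_d);
        vlv[irec] = y[ns - 1];
        ++irec;
      }
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
      deriv(net, ytmp, Etab[2 * s + 1], k2, netq, Pnode);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * dt * k2[i];
      deriv(net, ytmp, Etab[2 * s + 1], k3, netq, Pnode);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + dt * k3[i];
      deriv(net, ytmp, Etab[2 * s + 2], k4, netq, Pnode);
      for (int i = 0; i < ns; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (y[ns - 2] < 0.0) y[ns - 2] = 0.0; // valve closes on reverse flow
    }
    for (int n = 0; n < net.nn; ++n)
      if (!std::isfinite(y[n]) || std::fabs(y[n]) > 400.0) blew_up = true;
    if (have_prev) {
      double md = 0.0;
      for (int i = 0; i < n_out; ++i)
        for (int j = 0; j < nrp; ++j)
          md = std::max(md, std::fabs(Pout(i, j) - Pprev(i, j)));
      max_diff = md;
      if (md < tol && cycles_run >= min_cycles) converged = true;
    }
    std::copy(Pout.begin(), Pout.end(), Pprev.begin());
    have_prev = true;
  }

  return List::create(
    _["time"] = tout, _["pressure"] = Pout, _["flow"] = Qout,
    _["q_av"] = qav, _["p_lv"] = plv, _["v_lv"] = vlv,
    _["dt"] = dt, _["period"] = T, _["cycles_run"] = cycles_run,
    _["converged"] = converged, _["blew_up"] = blew_up,
    _["max_cycle_diff"] = max_diff);
}
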
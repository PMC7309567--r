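// Compartmental membrane-equation engine.
//
// Semi-implicit (theta-method, default Crank-Nicolson) update of the
// voltage on the compartment tree via a Hines-ordered direct solve;
// gating variables advanced by exponential Euler; dual-exponential
// synapses advanced analytically between presynaptic events.
//
// Units: mV, ms, uS, nF, nA internally; currents are reported in pA.
// Compartments must be ordered so that parent[i] < i (root = -1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

inline double powi(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

inline double boltz(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

// tau(v) = tmin + tamp / (exp((v-vt)/ka) + exp(-(v-vt)/kb)); tamp = 0 -> tmin
inline double taufun(double v, const double *g) {
  const double tmin = g[2], tamp = g[3];
  if (tamp <= 0.0) return tmin;
  return tmin + tamp / (std::exp((v - g[4]) / g[5]) + std::exp(-(v - g[4]) / g[6]));
}

struct Gate {
  // par = (vhalf, k, tmin, tamp, vt, ka, kb); ca-gated: (kd, unused, tau)
  double par[7];
  bool ca_gated;
  double inf(double v, double ca) const {
    if (ca_gated) return ca / (ca + par[0]);
    return boltz(v, par[0], par[1]);
  }
  double tau(double v) const {
    if (ca_gated) return par[2];
    return taufun(v, par);
  }
};

struct Channel {
  std::string name;
  std::vector<double> g;   // uS per compartment (density x area)
  double E;
  int p, q;
  Gate act, inact;
  bool is_ca;              // current feeds the calcium pool
  std::vector<double> m, h;
};

struct SynGroup {
  int comp;
  double E;
  double da, db, da2, db2; // per-step decay factors for A (rise) and B (decay)
  std::vector<double> ev_t, ev_w;
  std::size_t ptr;
  double A, B;
};

void fill_gate(Gate &gt, const NumericVector &v, bool ca_gated) {
  for (int i = 0; i < 7; ++i) gt.par[i] = (i < v.size()) ? v[i] : 0.0;
  gt.ca_gated = ca_gated;
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model, List protocol) {
  // ---- morphology / passive ----
  IntegerVector parent = model["parent"];
  NumericVector area   = model["area"];
  NumericVector cap    = model["cap"];      // nF
  NumericVector g_ax   = model["g_axial"];  // uS, coupling i <-> parent[i]
  const int n = parent.size();
  for (int i = 1; i < n; ++i)
    if (parent[i] < 0 || parent[i] >= i)
      stop("compartments must be ordered with parent[i] < i");

  // ---- channels ----
  List chl = model["channels"];
  const int nch = chl.size();
  std::vector<Channel> ch(nch);
  for (int c = 0; c < nch; ++c) {
    List cl = chl[c];
    ch[c].name = as<std::string>(cl["name"]);
    NumericVector gv = cl["g"];
    if (gv.size() != n) stop("channel '%s': conductance vector length mismatch", ch[c].name);
    ch[c].g.assign(gv.begin(), gv.end());
    ch[c].E = as<double>(cl["E"]);
    ch[c].p = as<int>(cl["p"]);
    ch[c].q = as<int>(cl["q"]);
    bool cag = as<bool>(cl["ca_gated"]);
    if (ch[c].p > 0) fill_gate(ch[c].act, cl["act"], cag);
    if (ch[c].q > 0) fill_gate(ch[c].inact, cl["inact"], false);
    ch[c].is_ca = as<bool>(cl["is_ca"]);
  }

  // ---- calcium pool ----
  List cal = model["ca"];
  const double ca_tau = as<double>(cal["tau"]);
  const double ca_rest = as<double>(cal["rest"]);
  const double ca_scale = as<double>(cal["scale"]);

  const double v_init = as<double>(model["v_init"]);

  // ---- protocol ----
  const double dt = as<double>(protocol["dt"]);
  const double duration = as<double>(protocol["duration"]);
  const int stride = as<int>(protocol["record_stride"]);
  IntegerVector sites = protocol["record_sites"];
  const int ns = sites.size();
  const double theta = as<double>(protocol["theta"]);
  if (dt <= 0 || duration <= 0) stop("duration and dt must be positive");

  List icl = protocol["iclamp"];
  std::vector<int> ic_comp; std::vector<double> ic_on, ic_off, ic_amp;
  for (int k = 0; k < icl.size(); ++k) {
    List s = icl[k];
    ic_comp.push_back(as<int>(s["comp"]));
    ic_on.push_back(as<double>(s["onset"]));
    ic_off.push_back(as<double>(s["offset"]));
    ic_amp.push_back(as<double>(s["amp"]));   // nA
  }

  bool has_vc = false; int vc_comp = -1; double vc_level = 0, vc_on = 0, vc_off = 0;
  if (!Rf_isNull(protocol["vclamp"])) {
    List vc = protocol["vclamp"];
    has_vc = true;
    vc_comp = as<int>(vc["comp"]);
    vc_level = as<double>(vc["level"]);
    vc_on = as<double>(vc["onset"]);
    vc_off = as<double>(vc["offset"]);
  }

  List sgl = protocol["syn_groups"];
  std::vector<SynGroup> syn(sgl.size());
  for (int k = 0; k < sgl.size(); ++k) {
    List s = sgl[k];
    SynGroup &g = syn[k];
    g.comp = as<int>(s["comp"]);
    g.E = as<double>(s["E"]);
    double tr = as<double>(s["tau_r"]), td = as<double>(s["tau_d"]);
    if (!(td > tr && tr > 0)) stop("synapse group %d: need tau_d > tau_r > 0", k + 1);
    g.da = std::exp(-dt / tr);  g.db = std::exp(-dt / td);
    g.da2 = std::exp(-0.5 * dt / tr); g.db2 = std::exp(-0.5 * dt / td);
    NumericVector t = s["ev_t"], w = s["ev_w"];
    g.ev_t.assign(t.begin(), t.end());
    g.ev_w.assign(w.begin(), w.end());
    g.ptr = 0; g.A = 0; g.B = 0;
  }

  // ---- state ----
  std::vector<double> V(n, v_init), ca(n, ca_rest);
  for (int c = 0; c < nch; ++c) {
    if (ch[c].p > 0) {
      ch[c].m.assign(n, 0.0);
      for (int i = 0; i < n; ++i) ch[c].m[i] = ch[c].act.inf(v_init, ca_rest);
    }
    if (ch[c].q > 0) {
      ch[c].h.assign(n, 0.0);
      for (int i = 0; i < n; ++i) ch[c].h[i] = ch[c].inact.inf(v_init, ca_rest);
    }
  }

  const long nsteps = (long)std::llround(duration / dt);
  const long nrec = nsteps / stride + 1;

  NumericMatrix vout(nrec, ns);
  NumericVector tout(nrec);
  std::vector<NumericMatrix> iout(nch);
  for (int c = 0; c < nch; ++c) iout[c] = NumericMatrix(nrec, ns);
  NumericMatrix ise(nrec, ns), isi(nrec, ns);  // synaptic currents, exc / inh split
  NumericVector iclamp_out(has_vc ? nrec : 0);

  // scratch
  std::vector<double> Gtot(n), Ssum(n), Iinj(n), diag(n), rhs(n), off(n);
  std::vector<double> gsyn_e(n), gsyn_i(n), se(n), si(n), ica(n);

  // record initial sample
  for (int s = 0; s < ns; ++s) vout(0, s) = V[sites[s]];
  tout[0] = 0.0;
  long irec = 1;

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const double tnew = t + dt;
    const bool vc_active = has_vc && (t >= vc_on - 1e-9) && (t < vc_off - 1e-9);
    if (vc_active) V[vc_comp] = vc_level;

    // -- gating update (exponential Euler at current V) --
    for (int c = 0; c < nch; ++c) {
      Channel &K = ch[c];
      if (K.p > 0) {
        if (K.act.ca_gated) {
          const double tau = K.act.par[2];
          const double e = std::exp(-dt / tau);
          for (int i = 0; i < n; ++i) {
            if (K.g[i] <= 0) continue;
            const double mi = K.act.inf(V[i], ca[i]);
            K.m[i] = mi + (K.m[i] - mi) * e;
          }
        } else {
          for (int i = 0; i < n; ++i) {
            if (K.g[i] <= 0) continue;
            const double mi = boltz(V[i], K.act.par[0], K.act.par[1]);
            const double tau = taufun(V[i], K.act.par);
            K.m[i] = mi + (K.m[i] - mi) * std::exp(-dt / tau);
          }
        }
      }
      if (K.q > 0) {
        for (int i = 0; i < n; ++i) {
          if (K.g[i] <= 0) continue;
          const double hi = boltz(V[i], K.inact.par[0], K.inact.par[1]);
          const double tau = taufun(V[i], K.inact.par);
          K.h[i] = hi + (K.h[i] - hi) * std::exp(-dt / tau);
        }
      }
    }

    // -- synapse states: deliver events, mid-step conductance --
    std::fill(gsyn_e.begin(), gsyn_e.end(), 0.0);
    std::fill(gsyn_i.begin(), gsyn_i.end(), 0.0);
    std::fill(se.begin(), se.end(), 0.0);
    std::fill(si.begin(), si.end(), 0.0);
    for (std::size_t k = 0; k < syn.size(); ++k) {
      SynGroup &g = syn[k];
      while (g.ptr < g.ev_t.size() && g.ev_t[g.ptr] <= t + 0.5 * dt) {
        g.A += g.ev_w[g.ptr];
        g.B += g.ev_w[g.ptr];
        ++g.ptr;
      }
      const double gmid = g.B * g.db2 - g.A * g.da2;
      if (gmid != 0.0) {
        if (g.E > -40.0) { gsyn_e[g.comp] += gmid; se[g.comp] += gmid * g.E; }
        else             { gsyn_i[g.comp] += gmid; si[g.comp] += gmid * g.E; }
      }
      g.A *= g.da; g.B *= g.db;
    }

    // -- assemble per-compartment totals --
    std::fill(Iinj.begin(), Iinj.end(), 0.0);
    for (std::size_t k = 0; k < ic_comp.size(); ++k)
      if (t >= ic_on[k] - 1e-9 && t < ic_off[k] - 1e-9) Iinj[ic_comp[k]] += ic_amp[k];

    std::fill(ica.begin(), ica.end(), 0.0);
    for (int i = 0; i < n; ++i) { Gtot[i] = gsyn_e[i] + gsyn_i[i]; Ssum[i] = se[i] + si[i]; }
    for (int c = 0; c < nch; ++c) {
      Channel &K = ch[c];
      for (int i = 0; i < n; ++i) {
        double gb = K.g[i];
        if (gb <= 0) continue;
        if (K.p > 0) gb *= powi(K.m[i], K.p);
        if (K.q > 0) gb *= powi(K.h[i], K.q);
        Gtot[i] += gb;
        Ssum[i] += gb * K.E;
        if (K.is_ca) ica[i] += gb * (V[i] - K.E);   // nA, inward negative
      }
    }

    // -- calcium pool (explicit exponential update) --
    if (ca_tau > 0) {
      const double e = std::exp(-dt / ca_tau);
      for (int i = 0; i < n; ++i) {
        const double influx = ica[i] < 0 ? ca_scale * (-ica[i]) / area[i] : 0.0;
        const double target = ca_rest + influx * ca_tau;
        ca[i] = target + (ca[i] - target) * e;
      }
    }

    // -- linear system (theta method) --
    for (int i = 0; i < n; ++i) {
      const double cdt = cap[i] / dt;
      diag[i] = cdt + theta * Gtot[i];
      rhs[i] = cdt * V[i] - (1.0 - theta) * Gtot[i] * V[i] + Ssum[i] + Iinj[i];
      off[i] = 0.0;
    }
    for (int i = 1; i < n; ++i) {
      const int j = parent[i];
      const double a = g_ax[i];
      diag[i] += theta * a; diag[j] += theta * a;
      rhs[i] += (1.0 - theta) * a * (V[j] - V[i]);
      rhs[j] += (1.0 - theta) * a * (V[i] - V[j]);
      off[i] = -theta * a;
    }

    if (vc_active) {
      // Dirichlet node: substitute known V at the clamped compartment
      for (int i = 1; i < n; ++i) {
        if (i == vc_comp && parent[i] >= 0) {
          rhs[parent[i]] += theta * g_ax[i] * vc_level; off[i] = 0.0;
        } else if (parent[i] == vc_comp) {
          rhs[i] += theta * g_ax[i] * vc_level; off[i] = 0.0;
        }
      }
      diag[vc_comp] = 1.0; rhs[vc_comp] = vc_level;
      if (vc_comp > 0) off[vc_comp] = 0.0;
    }

    // -- Hines solve (children have larger indices) --
    for (int i = n - 1; i >= 1; --i) {
      const double f = off[i] / diag[i];
      diag[parent[i]] -= f * off[i];
      rhs[parent[i]] -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] - off[i] * V[parent[i]]) / diag[i];
    if (vc_active) V[vc_comp] = vc_level;

    if ((step & 255) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 500.0)
          stop("voltage diverged at t = %.3f ms in compartment %d", tnew, i + 1);
    }

    // -- record --
    if ((step + 1) % stride == 0 && irec < nrec) {
      tout[irec] = tnew;
      for (int s = 0; s < ns; ++s) {
        const int i = sites[s];
        vout(irec, s) = V[i];
        for (int c = 0; c < nch; ++c) {
          Channel &K = ch[c];
          double gb = K.g[i];
          if (gb > 0) {
            if (K.p > 0) gb *= powi(K.m[i], K.p);
            if (K.q > 0) gb *= powi(K.h[i], K.q);
          }
          iout[c](irec, s) = 1e3 * gb * (V[i] - K.E);       // pA
        }
        ise(irec, s) = 1e3 * (gsyn_e[i] * V[i] - se[i]);    // g*(V-E) in pA
        isi(irec, s) = 1e3 * (gsyn_i[i] * V[i] - si[i]);
      }
      if (has_vc) {
        double icl_now = 0.0;
        if (vc_active) {
          // electrode current balancing ionic + axial flow at the node
          icl_now = Gtot[vc_comp] * vc_level - Ssum[vc_comp];
          if (vc_comp > 0)
            icl_now -= g_ax[vc_comp] * (V[parent[vc_comp]] - vc_level);
          for (int i = 1; i < n; ++i)
            if (parent[i] == vc_comp)
              icl_now -= g_ax[i] * (V[i] - vc_level);
        }
        iclamp_out[irec] = 1e3 * icl_now;                   // pA
      }
      ++irec;
    }
  }

  // gating sanity
  for (int c = 0; c < nch; ++c) {
    Channel &K = ch[c];
    for (int i = 0; i < n; ++i) {
      if (K.p > 0 && K.g[i] > 0 && (K.m[i] < -1e-9 || K.m[i] > 1.0 + 1e-9))
        stop("gating variable escaped [0,1] (channel %s)", K.name);
      if (K.q > 0 && K.g[i] > 0 && (K.h[i] < -1e-9 || K.h[i] > 1.0 + 1e-9))
        stop("gating variable escaped [0,1] (channel %s)", K.name);
    }
  }

  List cur(nch + 2);
  CharacterVector cn(nch + 2);
  for (int c = 0; c < nch; ++c) { cur[c] = iout[c]; cn[c] = ch[c].name; }
  cur[nch] = ise; cn[nch] = "syn_exc";
  cur[nch + 1] = isi; cn[nch + 1] = "syn_inh";
  cur.attr("names") = cn;

  NumericVector vfinal(V.begin(), V.end());
  return List::create(
    _["time"] = tout,
    _["v"] = vout,
    _["currents"] = cur,
    _["iclamp"] = has_vc ? (RObject)iclamp_out : (RObject)R_NilValue,
    _["v_final"] = vfinal);
}
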
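// Implicit branched-cable integrator.
//
// Solves C_i dV_i/dt = -I_ion,i - I_axial,i + I_inj,i on a compartment tree
// with Hodgkin-Huxley style channels.  Gating variables are advanced with
// the exponential (Rush-Larsen) update from voltage-indexed lookup tables
// built in R; the voltage step is a theta-method (theta = 1: backward
// Euler; theta = 0.5: Crank-Nicolson-like) solved exactly on the tree with
// one leaf-to-root elimination sweep per step (Hines ordering: parent index
// strictly less than child index).
//
// Units: V mV, t ms, capacitance nF, conductance uS, current nA.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct GateTab {
  int exponent;
  std::vector<double> inf, efac; // efac = exp(-dt/tau) on the voltage grid
};

struct Chan {
  double erev;
  std::vector<double> gbar;      // uS per compartment
  std::vector<GateTab> gates;
  std::vector<int> comps;        // compartments with gbar > 0
};

static inline void table_lookup(const std::vector<double>& tab, double u,
                                int n, double& out) {
  // u is a fractional index into the table
  if (u <= 0) { out = tab[0]; return; }
  if (u >= n - 1) { out = tab[n - 1]; return; }
  int i = (int)u;
  double w = u - i;
  out = (1 - w) * tab[i] + w * tab[i + 1];
}

// [[Rcpp::export(name = ".cable_sim")]]
List cable_sim(List sys, List stim, List init, double dt, int n_steps,
               IntegerVector record, double theta, double t0,
               double record_stride) {
  IntegerVector parent = sys["parent"];      // 0-based, -1 for root
  NumericVector g_ax = sys["g_ax"];          // uS toward parent
  NumericVector cap = sys["cap"];            // nF
  NumericVector g_pas = sys["g_pas"];        // uS
  NumericVector e_pas = sys["e_pas"];        // mV
  double vmin = sys["vmin"], vstep = sys["vstep"];
  int ntab = sys["ntab"];
  List channels = sys["channels"];

  const int n = parent.size();
  std::vector<Chan> chans;
  for (int c = 0; c < channels.size(); ++c) {
    List ch = channels[c];
    Chan C;
    C.erev = ch["erev"];
    NumericVector gb = ch["gbar"];
    C.gbar.assign(gb.begin(), gb.end());
    for (int i = 0; i < n; ++i) if (C.gbar[i] > 0) C.comps.push_back(i);
    List gl = ch["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List gg = gl[g];
      GateTab G;
      G.exponent = gg["exponent"];
      NumericVector inf = gg["inf"], ef = gg["efac"];
      G.inf.assign(inf.begin(), inf.end());
      G.efac.assign(ef.begin(), ef.end());
      C.gates.push_back(G);
    }
    if (!C.comps.empty()) chans.push_back(C);
  }

  // stimulation
  NumericMatrix pulses = stim["pulses"];     // comp(0-based), onset, dur, amp nA
  List synapses = stim["synapses"];          // comp, e, tau1, tau2, weight, factor, onsets
  NumericVector noise = stim["noise"];       // nA per step (length 0 or n_steps)
  int noise_comp = stim["noise_comp"];       // 0-based, -1 if none

  // state
  NumericVector V0 = init["V"];
  std::vector<double> V(V0.begin(), V0.end());
  List gate0 = init["gates"];                // per channel: matrix n x ngates
  std::vector<std::vector<double>> gstate(chans.size());
  {
    int ci = 0;
    for (int c = 0; c < channels.size(); ++c) {
      List ch = channels[c];
      NumericVector gb = ch["gbar"];
      bool any = false;
      for (int i = 0; i < n; ++i) if (gb[i] > 0) { any = true; break; }
      if (!any) continue;
      NumericMatrix gm = gate0[c];
      gstate[ci].assign(gm.begin(), gm.end()); // column-major: gate-major blocks of n
      ++ci;
    }
  }

  const int nrec = record.size();
  int n_out = (int)(n_steps / record_stride) + 1;
  NumericMatrix out(n_out, nrec);
  NumericVector tout(n_out);
  for (int r = 0; r < nrec; ++r) out(0, r) = V[record[r]];
  tout[0] = t0;
  int outrow = 1;

  std::vector<double> gtot(n), ge(n), d(n), rhs(n), iax_old(n);

  for (int step = 1; step <= n_steps; ++step) {
    double t_new = t0 + step * dt;

    // 1. gating update (Rush-Larsen at previous voltage)
    for (size_t c = 0; c < chans.size(); ++c) {
      Chan& C = chans[c];
      int ngate = C.gates.size();
      for (int g = 0; g < ngate; ++g) {
        GateTab& G = C.gates[g];
        double* x = &gstate[c][(size_t)g * n];
        for (size_t k = 0; k < C.comps.size(); ++k) {
          int i = C.comps[k];
          double u = (V[i] - vmin) / vstep;
          double inf, ef;
          table_lookup(G.inf, u, ntab, inf);
          table_lookup(G.efac, u, ntab, ef);
          x[i] = inf + (x[i] - inf) * ef;
        }
      }
    }

    // 2. membrane conductances
    for (int i = 0; i < n; ++i) {
      gtot[i] = g_pas[i];
      ge[i] = g_pas[i] * e_pas[i];
    }
    for (size_t c = 0; c < chans.size(); ++c) {
      Chan& C = chans[c];
      int ngate = C.gates.size();
      for (size_t k = 0; k < C.comps.size(); ++k) {
        int i = C.comps[k];
        double g = C.gbar[i];
        for (int gg = 0; gg < ngate; ++gg) {
          double x = gstate[c][(size_t)gg * n + i];
          int e = C.gates[gg].exponent;
          double xp = x;
          for (int q = 1; q < e; ++q) xp *= x;
          g *= xp;
        }
        gtot[i] += g;
        ge[i] += g * C.erev;
      }
    }

    // 3. synaptic conductances at t_new
    for (int s = 0; s < synapses.size(); ++s) {
      List sy = synapses[s];
      int comp = sy["comp"];
      double e = sy["e"], tau1 = sy["tau1"], tau2 = sy["tau2"];
      double w = sy["weight"], factor = sy["factor"];
      NumericVector onsets = sy["onsets"];
      double G = 0;
      for (int o = 0; o < onsets.size(); ++o) {
        double td = t_new - onsets[o];
        if (td > 0) G += w * factor * (std::exp(-td / tau2) - std::exp(-td / tau1));
      }
      if (G > 0) { gtot[comp] += G; ge[comp] += G * e; }
    }

    // 4. injected current at t_new (nA)
    std::vector<double> inj(n, 0.0);
    for (int p = 0; p < pulses.nrow(); ++p) {
      double on = pulses(p, 1), dur = pulses(p, 2);
      if (t_new > on && t_new <= on + dur + 1e-12)
        inj[(int)pulses(p, 0)] += pulses(p, 3);
    }
    if (noise_comp >= 0 && noise.size() >= n_steps)
      inj[noise_comp] += noise[step - 1];

    // 5. assemble theta-method tree system
    if (theta < 1.0) {
      for (int i = 0; i < n; ++i) iax_old[i] = 0;
      for (int i = 1; i < n; ++i) {
        int p = parent[i];
        double f = g_ax[i] * (V[i] - V[p]);
        iax_old[i] += f;
        iax_old[p] -= f;
      }
    }
    // C/dt (V' - V) = -theta [gtot V' - ge + Iax(V')]
    //                 - (1-theta) [gtot V - ge + Iax(V)] + inj
    for (int i = 0; i < n; ++i) {
      d[i] = cap[i] / dt + theta * gtot[i];
      rhs[i] = cap[i] / dt * V[i] + ge[i] + inj[i];
      if (theta < 1.0)
        rhs[i] -= (1 - theta) * (gtot[i] * V[i] + iax_old[i]);
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      d[i] += theta * g_ax[i];
      d[p] += theta * g_ax[i];
    }
    // elimination: leaves to root (parent[i] < i guaranteed)
    std::vector<double> off(n);
    for (int i = 1; i < n; ++i) off[i] = -theta * g_ax[i];
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = off[i] / d[i];
      d[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    std::vector<double> Vn(n);
    Vn[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      Vn[i] = (rhs[i] - off[i] * Vn[parent[i]]) / d[i];
    V = Vn;

    if ((step & 127) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]))
          stop("numerical failure (non-finite voltage) at t = %f ms, compartment %d",
               t_new, i + 1);
    }

    if (step % (int)record_stride == 0 && outrow < n_out) {
      for (int r = 0; r < nrec; ++r) out(outrow, r) = V[record[r]];
      tout[outrow] = t_new;
      ++outrow;
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(V[i]))
      stop("numerical failure (non-finite voltage) at end of simulation");

  // final state (for warm restarts)
  List gates_out(channels.size());
  {
    int ci = 0;
    for (int c = 0; c < channels.size(); ++c) {
      List ch = channels[c];
      NumericVector gb = ch["gbar"];
      bool any = false;
      for (int i = 0; i < n; ++i) if (gb[i] > 0) { any = true; break; }
      List gl = ch["gates"];
      int ngate = gl.size();
      NumericMatrix gm(n, ngate);
      if (any) {
        std::copy(gstate[ci].begin(), gstate[ci].end(), gm.begin());
        ++ci;
      }
      gates_out[c] = gm;
    }
  }
  return List::create(_["t"] = tout, _["V"] = out,
                      _["state"] = List::create(_["V"] = NumericVector(V.begin(), V.end()),
                                                _["gates"] = gates_out));
}
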
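// Fixed-step (exponential-Euler) conductance-based LIF network simulator with
// stochastic multivesicular Tsodyks-Markram synapses, per-neuron OU
// conductance injection, somatic current pulses and external spike sources.
//
// Units: time ms, voltage mV, conductance nS, current nA, capacitance pF.
// nS * mV = pA; dV[mV] = I[pA] * dt[ms] / C[pF].

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Event {
  int post;
  int grp;
  double w; // peak-normalised conductance increment (nS)
};

// peak of exp(-t/taud) - exp(-t/taur) for taud > taur > 0
double biexp_peak(double taur, double taud) {
  if (taur <= 0.0) return 1.0; // pure exponential decay, jump amplitude is peak
  double tp = (taud * taur / (taud - taur)) * std::log(taud / taur);
  return std::exp(-tp / taud) - std::exp(-tp / taur);
}

double mg_block(double v, double mg_mM) {
  // Jahr-Stevens sigmoidal voltage dependence of the NMDA Mg2+ block
  return 1.0 / (1.0 + (mg_mM / 3.57) * std::exp(-0.062 * v));
}

// exp(-x) for x >= 0; series branch for the tiny exponents of the
// per-step membrane update (relative error < 1e-9 for x < 0.02)
inline double exp_neg(double x) {
  if (x < 0.02) {
    double x2 = x * x;
    return 1.0 - x + 0.5 * x2 - x2 * x / 6.0;
  }
  return std::exp(-x);
}

// piecewise-linear table of the Mg-block factor over the admissible
// voltage range
struct MgTable {
  double v0, dv;
  std::vector<double> f;
  void init(double mg_mM) {
    v0 = -120.0; dv = 0.05;
    int m = (int) ((80.0 - v0) / dv) + 2;
    f.resize(m);
    for (int i = 0; i < m; ++i) f[i] = mg_block(v0 + i * dv, mg_mM);
  }
  inline double at(double v) const {
    double u = (v - v0) / dv;
    if (u <= 0.0) return f.front();
    int i = (int) u;
    if (i + 1 >= (int) f.size()) return f.back();
    double w = u - i;
    return f[i] * (1.0 - w) + f[i + 1] * w;
  }
};

// Fast normal generator for the high-volume OU innovations: Marsaglia-Tsang
// ziggurat (128 layers) over a 32-bit stream drawn from mt19937_64.
struct Ziggurat {
  std::mt19937_64 *rng;
  uint32_t kn[128];
  double wn[128], fn[128];
  uint64_t buf;
  bool have;
  void init(std::mt19937_64 *r) {
    rng = r; have = false; buf = 0;
    double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3, q;
    q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline uint32_t next32() {
    if (have) { have = false; return (uint32_t)(buf >> 32); }
    buf = (*rng)();
    have = true;
    return (uint32_t) buf;
  }
  inline double unif() { return (next32() + 0.5) * (1.0 / 4294967296.0); }
  double nfix(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    double x, y;
    for (;;) {
      x = hz * wn[iz];
      if (iz == 0) { // base-strip tail
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      hz = (int32_t) next32();
      iz = hz & 127;
      if ((uint32_t) std::abs(hz) < kn[iz]) return hz * wn[iz];
    }
  }
  inline double rnorm() {
    int32_t hz = (int32_t) next32();
    uint32_t iz = hz & 127;
    return ((uint32_t) std::abs(hz) < kn[iz]) ? hz * wn[iz] : nfix(hz, iz);
  }
};

int rbinom_int(std::mt19937_64 &rng, Ziggurat &zig, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if (n <= 64) { // fast path: the pools in play are small
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (zig.unif() < p) ++k;
    return k;
  }
  std::binomial_distribution<int> d(n, p);
  return d(rng);
}

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List net, List cfg) {
  // ---- network unpacking ----
  const int n = as<int>(net["n"]);
  NumericVector Cm = net["C"], gL = net["gL"], EL = net["EL"], Vth = net["Vth"],
                Vreset = net["Vreset"], tref = net["tref"];
  NumericVector Eexc = net["Eexc"], Einh = net["Einh"];

  IntegerVector e_pre = net["edge_pre"];   // 1-based over sources (1..n internal, n+1.. external)
  IntegerVector e_post = net["edge_post"]; // 1-based internal neuron
  NumericVector e_nsyn = net["edge_nsyn"];
  NumericVector e_delay = net["edge_delay"];
  IntegerVector e_path = net["edge_path"]; // 1-based pathway
  const int n_edges = e_pre.size();
  const int n_ext = as<int>(net["n_ext"]);
  const int n_src = n + n_ext;

  // pathway parameters
  NumericVector p_use = net["p_use"], p_D = net["p_D"], p_F = net["p_F"],
                p_nrrp = net["p_nrrp"], p_uhill = net["p_uhill"],
                p_ghat = net["p_ghat"], p_gratio = net["p_gratio"],
                p_spont = net["p_spont"];
  LogicalVector p_quantal_pool = net["p_quantal_pool"]; // TRUE: ghat split over NRRP
  IntegerVector path_grp = net["path_grp"];             // 1-based conductance group
  IntegerVector path_nmda_grp = net["path_nmda_grp"];   // 0 = none
  NumericVector g_taur = net["grp_taur"], g_taud = net["grp_taud"],
                g_erev = net["grp_erev"];
  LogicalVector g_nmda = net["grp_nmda"];
  const int n_grp = g_taur.size();
  const int n_path = p_use.size();

  // ---- config ----
  const double dt = as<double>(cfg["dt"]);
  const double duration = as<double>(cfg["duration"]);
  const unsigned long seed = (unsigned long) as<double>(cfg["seed"]);
  const double calcium = as<double>(cfg["calcium"]);
  const double hill_k = as<double>(cfg["hill_k"]);
  const double mg_mM = as<double>(cfg["mg"]);
  NumericVector ou_g0 = cfg["ou_g0"], ou_sigma = cfg["ou_sigma"];
  const double ou_tau = as<double>(cfg["ou_tau"]);
  const double ou_erev = as<double>(cfg["ou_erev"]);
  NumericVector tonic_g = cfg["tonic_g"];
  const double tonic_erev = as<double>(cfg["tonic_erev"]);
  NumericMatrix pulses = cfg["pulses"]; // cols: neuron(1b), amp_nA, onset, dur, ramp
  IntegerVector ext_src = cfg["ext_spk_src"]; // 1-based source index (n+1..n_src)
  NumericVector ext_t = cfg["ext_spk_t"];     // sorted by time
  IntegerVector rec_ids = cfg["record_v"];    // 1-based
  const bool record_g = as<bool>(cfg["record_g"]);
  const int stride = as<int>(cfg["record_stride"]);
  const bool spont_depletes = as<bool>(cfg["spont_depletes"]);
  NumericVector v_init = cfg["v_init"];

  const int n_steps = (int) std::llround(duration / dt);
  MgTable mgt;
  mgt.init(mg_mM);
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  Ziggurat zig;
  zig.init(&rng);

  // ---- derived pathway quantities ----
  std::vector<double> ueff(n_path), wves(n_path), norm_grp(n_grp);
  for (int g = 0; g < n_grp; ++g) norm_grp[g] = 1.0 / biexp_peak(g_taur[g], g_taud[g]);
  const double hill_ref = std::pow(2.0, 1.0); // placeholder, computed per pathway below
  (void)hill_ref;
  for (int p = 0; p < n_path; ++p) {
    double h = p_uhill[p];
    double scale = 1.0;
    if (h > 0.0 && hill_k > 0.0) {
      double num = std::pow(calcium, h) / (std::pow(calcium, h) + std::pow(hill_k, h));
      double den = std::pow(2.0, h) / (std::pow(2.0, h) + std::pow(hill_k, h));
      scale = num / den;
    }
    ueff[p] = std::min(1.0, p_use[p] * scale);
    wves[p] = p_quantal_pool[p] ? (p_ghat[p] / std::max(1.0, p_nrrp[p])) : p_ghat[p];
  }

  // ---- adjacency CSR over sources ----
  std::vector<int> out_start(n_src + 1, 0), out_edge(n_edges);
  {
    std::vector<int> cnt(n_src, 0);
    for (int e = 0; e < n_edges; ++e) cnt[e_pre[e] - 1]++;
    for (int s = 0; s < n_src; ++s) out_start[s + 1] = out_start[s] + cnt[s];
    std::vector<int> pos(out_start.begin(), out_start.end() - 1);
    for (int e = 0; e < n_edges; ++e) out_edge[pos[e_pre[e] - 1]++] = e;
  }

  // ---- TM synapse state per edge ----
  std::vector<int> npool(n_edges), avail(n_edges);
  std::vector<double> uvar(n_edges, 0.0), tlast(n_edges, 0.0);
  int max_delay_steps = 1;
  std::vector<int> delay_steps(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    npool[e] = std::max(1, (int) std::llround(p_nrrp[e_path[e] - 1] * e_nsyn[e]));
    avail[e] = npool[e];
    delay_steps[e] = std::max(1, (int) std::llround(e_delay[e] / dt));
    if (delay_steps[e] > max_delay_steps) max_delay_steps = delay_steps[e];
  }

  // event ring buffer
  const int nb = max_delay_steps + 1;
  std::vector<std::vector<Event>> buckets(nb);

  // ---- spontaneous release events (pre-drawn, delivered bucket-wise) ----
  // schedule: (step, edge); stored sorted by step
  std::vector<std::pair<int, int>> spont;
  for (int e = 0; e < n_edges; ++e) {
    double rate = p_spont[e_path[e] - 1] * e_nsyn[e]; // Hz aggregated over contacts
    if (rate <= 0.0) continue;
    double lambda = rate * duration / 1000.0;
    std::poisson_distribution<int> pois(lambda);
    int k = pois(rng);
    for (int i = 0; i < k; ++i) {
      int s = (int) std::floor(runif01(rng) * n_steps);
      if (s >= n_steps) s = n_steps - 1;
      spont.push_back(std::make_pair(s, e));
    }
  }
  std::sort(spont.begin(), spont.end());
  size_t spont_ix = 0;

  // ---- per-neuron conductance states (A: decay, B: rise), column-major [n x n_grp] ----
  std::vector<double> Agrp((size_t) n * n_grp, 0.0), Bgrp((size_t) n * n_grp, 0.0);
  std::vector<double> dec_d(n_grp), dec_r(n_grp);
  for (int g = 0; g < n_grp; ++g) {
    dec_d[g] = std::exp(-dt / g_taud[g]);
    dec_r[g] = g_taur[g] > 0.0 ? std::exp(-dt / g_taur[g]) : 0.0;
  }

  // ---- OU state ----
  std::vector<double> ou(n);
  const double ou_a = std::exp(-dt / ou_tau);
  const double ou_b = std::sqrt(1.0 - ou_a * ou_a);
  bool any_ou = false;
  for (int i = 0; i < n; ++i) {
    ou[i] = ou_g0[i];
    if (ou_g0[i] > 0.0 || ou_sigma[i] > 0.0) any_ou = true;
  }

  // ---- pulses grouped by neuron ----
  std::vector<std::vector<int>> pulse_of(n);
  for (int r = 0; r < pulses.nrow(); ++r) {
    int pn = (int) pulses(r, 0);
    if (pn < 1 || pn > n)
      stop("pulse neuron id %d outside 1..%d", pn, n);
    pulse_of[pn - 1].push_back(r);
  }

  // ---- neuron state ----
  std::vector<double> V(n);
  std::vector<int> ref_left(n, 0);
  for (int i = 0; i < n; ++i) V[i] = v_init[i];

  // ---- recording ----
  const int n_rec = rec_ids.size();
  const int n_samples = n_steps / stride + 1;
  NumericMatrix vtrace(n_rec > 0 ? n_samples : 0, n_rec);
  NumericMatrix getrace(record_g && n_rec > 0 ? n_samples : 0, record_g ? n_rec : 0);
  NumericMatrix gitrace(record_g && n_rec > 0 ? n_samples : 0, record_g ? n_rec : 0);
  std::vector<int> rec_map(n, -1);
  for (int r = 0; r < n_rec; ++r) {
    if (rec_ids[r] < 1 || rec_ids[r] > n)
      stop("recorded neuron id %d outside 1..%d", rec_ids[r], n);
    rec_map[rec_ids[r] - 1] = r;
  }

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  std::vector<int> spiking;
  size_t ext_ix = 0;

  // record initial sample
  for (int r = 0; r < n_rec; ++r) vtrace(0, r) = V[rec_ids[r] - 1];

  // TM update + release at time t for edge e; kind 0 = presyn spike, 1 = spontaneous
  auto tm_fire = [&](int e, double t, int kind) {
    int p = e_path[e] - 1;
    double dtl = t - tlast[e];
    if (dtl > 0.0) {
      int missing = npool[e] - avail[e];
      if (missing > 0) {
        double pr = (p_D[p] > 0.0) ? (1.0 - std::exp(-dtl / p_D[p])) : 1.0;
        avail[e] += rbinom_int(rng, zig, missing, pr);
      }
      uvar[e] = (p_F[p] > 0.0) ? uvar[e] * std::exp(-dtl / p_F[p]) : 0.0;
      tlast[e] = t;
    }
    int released = 0;
    if (kind == 0) {
      uvar[e] = uvar[e] + ueff[p] * (1.0 - uvar[e]);
      released = rbinom_int(rng, zig, avail[e], uvar[e]);
      avail[e] -= released;
    } else {
      if (avail[e] > 0) {
        released = 1;
        if (spont_depletes) avail[e] -= 1;
      }
    }
    if (released > 0) {
      double w = released * wves[p];
      int g = path_grp[p] - 1;
      int target_step_off = (kind == 0) ? delay_steps[e] : 1;
      int cur = (int) std::llround(t / dt);
      int bix = (cur + target_step_off) % nb;
      if (cur + target_step_off <= n_steps) {
        Event ev; ev.post = e_post[e] - 1; ev.grp = g; ev.w = w * norm_grp[g];
        buckets[bix].push_back(ev);
        if (path_nmda_grp[p] > 0 && p_gratio[p] > 0.0) {
          int gn = path_nmda_grp[p] - 1;
          Event evn; evn.post = ev.post; evn.grp = gn; evn.w = w * p_gratio[p] * norm_grp[gn];
          buckets[bix].push_back(evn);
        }
      }
    }
  };

  // ---- main loop ----
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // deliver conductance events scheduled for this step
    {
      std::vector<Event> &bk = buckets[s % nb];
      for (size_t i = 0; i < bk.size(); ++i) {
        size_t ix = (size_t) bk[i].grp * n + bk[i].post;
        Agrp[ix] += bk[i].w;
        Bgrp[ix] += bk[i].w;
      }
      bk.clear();
    }

    // spontaneous releases at this step
    while (spont_ix < spont.size() && spont[spont_ix].first == s) {
      tm_fire(spont[spont_ix].second, t, 1);
      ++spont_ix;
    }

    // forced external source spikes at (approximately) this step
    while (ext_ix < (size_t) ext_src.size() && ext_t[ext_ix] < t + dt) {
      int src = ext_src[ext_ix] - 1;
      for (int k = out_start[src]; k < out_start[src + 1]; ++k)
        tm_fire(out_edge[k], t, 0);
      ++ext_ix;
    }

    // integrate neurons
    spiking.clear();
    for (int i = 0; i < n; ++i) {
      // synaptic conductances
      double gtot = gL[i];
      double gE = EL[i] * gL[i];
      for (int g = 0; g < n_grp; ++g) {
        double gc = Agrp[(size_t) g * n + i] - Bgrp[(size_t) g * n + i];
        if (gc <= 0.0) continue;
        if (g_nmda[g]) gc *= mgt.at(V[i]);
        gtot += gc;
        gE += gc * g_erev[g];
      }
      if (any_ou) {
        double gou = ou[i] > 0.0 ? ou[i] : 0.0; // clipped at injection
        gtot += gou;
        gE += gou * ou_erev;
        // advance OU (exact discretisation of the stationary process)
        if (ou_sigma[i] > 0.0)
          ou[i] = ou_g0[i] + (ou[i] - ou_g0[i]) * ou_a + ou_sigma[i] * ou_b * zig.rnorm();
      }
      if (tonic_g[i] > 0.0) {
        gtot += tonic_g[i];
        gE += tonic_g[i] * tonic_erev;
      }
      // injected current pulses (nA -> pA)
      double Ipa = 0.0;
      const std::vector<int> &pls = pulse_of[i];
      for (size_t q = 0; q < pls.size(); ++q) {
        double amp = pulses(pls[q], 1), on = pulses(pls[q], 2),
               dur = pulses(pls[q], 3), ramp = pulses(pls[q], 4);
        if (t >= on && t < on + dur) Ipa += amp * 1000.0;
        else if (ramp > 0.0 && t >= on + dur && t < on + dur + ramp)
          Ipa += amp * 1000.0 * (1.0 - (t - on - dur) / ramp);
      }

      if (ref_left[i] > 0) {
        --ref_left[i];
        V[i] = Vreset[i];
      } else {
        double vinf = (gE + Ipa) / gtot;
        V[i] = vinf + (V[i] - vinf) * exp_neg(dt * gtot / Cm[i]);
        if (!std::isfinite(V[i]))
          stop("numerical divergence: non-finite membrane potential (neuron %d, t = %.2f ms)",
               i + 1, t);
        if (V[i] >= Vth[i]) {
          spk_id.push_back(i + 1);
          spk_t.push_back(t + dt);
          V[i] = Vreset[i];
          ref_left[i] = (int) std::llround(tref[i] / dt);
          spiking.push_back(i);
        }
      }
    }

    // propagate internal spikes
    for (size_t q = 0; q < spiking.size(); ++q) {
      int src = spiking[q];
      for (int k = out_start[src]; k < out_start[src + 1]; ++k)
        tm_fire(out_edge[k], t + dt, 0);
    }

    // decay conductance states
    for (int g = 0; g < n_grp; ++g) {
      double dd = dec_d[g], dr = dec_r[g];
      double *A = &Agrp[(size_t) g * n];
      double *B = &Bgrp[(size_t) g * n];
      for (int i = 0; i < n; ++i) { A[i] *= dd; B[i] *= dr; }
    }

    // record
    if ((s + 1) % stride == 0) {
      int row = (s + 1) / stride;
      if (row < n_samples) {
        for (int r = 0; r < n_rec; ++r) {
          int i = rec_ids[r] - 1;
          vtrace(row, r) = V[i];
          if (record_g) {
            double ge_sum = 0.0, gi_sum = 0.0;
            for (int g = 0; g < n_grp; ++g) {
              double gc = Agrp[(size_t) g * n + i] - Bgrp[(size_t) g * n + i];
              if (gc <= 0.0) continue;
              if (g_nmda[g]) gc *= mg_block(V[i], mg_mM);
              if (g_erev[g] > Einh[i] + 30.0) ge_sum += gc; else gi_sum += gc;
            }
            getrace(row, r) = ge_sum;
            gitrace(row, r) = gi_sum;
          }
        }
      }
    }
  }

  List out = List::create(
      _["spike_id"] = wrap(spk_id), _["spike_t"] = wrap(spk_t),
      _["v"] = vtrace, _["ge"] = getrace, _["gi"] = gitrace,
      _["n_steps"] = n_steps);
  return out;
}
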
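// Node-level simulation kernel: time-driven neuron update, event-driven
// synaptic delivery through per-unit ring buffers with valid-timestamp
// (k_val) invalidation, deterministic spike serialization.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include "fixedpoint.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// XNOR-shift PRNG: complemented Marsaglia xorshift triplet (13, 17, 5)
static inline uint32_t xns_next(uint32_t x) {
  x = ~(x ^ (x << 13));
  x = ~(x ^ (x >> 17));
  x = ~(x ^ (x << 5));
  return x;
}

// [[Rcpp::export]]
List xnorshift_cpp(double state, int n) {
  uint32_t s = static_cast<uint32_t>(state);
  NumericVector states(n), values(n);
  for (int i = 0; i < n; ++i) {
    s = xns_next(s);
    states[i] = static_cast<double>(s);
    values[i] = static_cast<double>(s) / 4294967296.0;
  }
  return List::create(_["state"] = states, _["value"] = values);
}

// ---------------------------------------------------------------------------
// Single forward-Euler step, h = 0.1 ms, both arithmetic modes.
// Fixed mode documents the reference evaluation order of 0.04 v^2 + 5 v + 140:
// v*v first, scaled by 0.04, then + 5 v, + 140, - u, + currents; both state
// derivatives are evaluated on the pre-update state.

struct FxConsts {
  int64_t c004, c5, c140, h, thr;
  FxConsts() {
    int s = 0;
    (void)s;
    c004 = fx::enc(0.04);
    c5   = fx::enc(5.0);
    c140 = fx::enc(140.0);
    h    = fx::enc(0.1);
    thr  = fx::enc(30.0);
  }
};
static const FxConsts FXC;

static inline int64_t euler_fx(int64_t& v, int64_t& u,
                               int64_t a, int64_t b, int64_t c, int64_t d,
                               int64_t iex, int64_t iinh, int64_t iext,
                               int& sat, bool& spiked) {
  int64_t acc = fx::mul(FXC.c004, fx::mul(v, v, sat), sat);
  acc = fx::add(acc, fx::mul(FXC.c5, v, sat), sat);
  acc = fx::add(acc, FXC.c140, sat);
  acc = fx::add(acc, -u, sat);
  acc = fx::add(acc, iex, sat);
  acc = fx::add(acc, iinh, sat);
  acc = fx::add(acc, iext, sat);
  int64_t v1 = fx::add(v, fx::mul(FXC.h, acc, sat), sat);
  int64_t tu = fx::add(fx::mul(b, v, sat), -u, sat);
  int64_t u1 = fx::add(u, fx::mul(FXC.h, fx::mul(a, tu, sat), sat), sat);
  int64_t v_report;
  if (v1 >= FXC.thr) {
    spiked = true;
    v_report = FXC.thr; // spike-peak normalization
    v1 = c;
    u1 = fx::add(u1, d, sat);
  } else {
    spiked = false;
    v_report = v1;
  }
  v = v1;
  u = u1;
  return v_report;
}

static inline double euler_fl(double& v, double& u,
                              double a, double b, double c, double d,
                              double iex, double iinh, double iext,
                              bool& spiked) {
  double acc = 0.04 * v * v + 5.0 * v + 140.0 - u + iex + iinh + iext;
  double v1 = v + 0.1 * acc;
  double u1 = u + 0.1 * (a * (b * v - u));
  double v_report;
  if (v1 >= 30.0) {
    spiked = true;
    v_report = 30.0;
    v1 = c;
    u1 = u1 + d;
  } else {
    spiked = false;
    v_report = v1;
  }
  v = v1;
  u = u1;
  return v_report;
}

// [[Rcpp::export]]
List euler_step_cpp(NumericVector v, NumericVector u,
                    NumericVector a, NumericVector b,
                    NumericVector c, NumericVector d,
                    NumericVector iex, NumericVector iinh, NumericVector iext,
                    bool fixed) {
  R_xlen_t n = v.size();
  NumericVector v1(n), u1(n), vrep(n);
  LogicalVector sp(n);
  int sat = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    bool spiked = false;
    if (fixed) {
      int64_t vv = fx::enc(v[i]), uu = fx::enc(u[i]);
      int64_t rep = euler_fx(vv, uu,
                             fx::enc(a[i]), fx::enc(b[i]), fx::enc(c[i]), fx::enc(d[i]),
                             fx::enc(iex[i]), fx::enc(iinh[i]), fx::enc(iext[i]),
                             sat, spiked);
      v1[i] = vv / fx::SCALE;
      u1[i] = uu / fx::SCALE;
      vrep[i] = rep / fx::SCALE;
    } else {
      double vv = v[i], uu = u[i];
      double rep = euler_fl(vv, uu, a[i], b[i], c[i], d[i],
                            iex[i], iinh[i], iext[i], spiked);
      v1[i] = vv;
      u1[i] = uu;
      vrep[i] = rep;
    }
    sp[i] = spiked;
  }
  return List::create(_["v"] = v1, _["u"] = u1, _["v_reported"] = vrep,
                      _["spiked"] = sp, _["saturations"] = sat);
}

// Single-neuron trajectory without re-encoding state between steps
// (pipeline-faithful: state stays in raw s16.23 across the whole run).
// [[Rcpp::export]]
List izh_run_cpp(double a, double b, double c, double d,
                 double v0, double u0, NumericVector i_ext,
                 int steps, bool fixed) {
  NumericVector v_trace(steps), u_trace(steps);
  std::vector<int> spikes;
  int sat = 0;
  if (fixed) {
    int64_t v = fx::enc(v0), u = fx::enc(u0);
    int64_t ra = fx::enc(a), rb = fx::enc(b), rc = fx::enc(c), rd = fx::enc(d);
    for (int k = 0; k < steps; ++k) {
      bool spiked = false;
      int64_t iext = fx::enc(i_ext[k % i_ext.size()]);
      int64_t rep = euler_fx(v, u, ra, rb, rc, rd, 0, 0, iext, sat, spiked);
      v_trace[k] = rep / fx::SCALE;
      u_trace[k] = u / fx::SCALE;
      if (spiked) spikes.push_back(k);
    }
  } else {
    double v = v0, u = u0;
    for (int k = 0; k < steps; ++k) {
      bool spiked = false;
      double rep = euler_fl(v, u, a, b, c, d, 0.0, 0.0,
                            i_ext[k % i_ext.size()], spiked);
      v_trace[k] = rep;
      u_trace[k] = u;
      if (spiked) spikes.push_back(k);
    }
  }
  return List::create(_["v"] = v_trace, _["u"] = u_trace,
                      _["spike_steps"] = wrap(spikes),
                      _["saturations"] = sat);
}

// ---------------------------------------------------------------------------
// Full node kernel.
// Per step k: (1) per-slot ring-buffer read (k_val check) + Euler update;
// (2) spikes serialized in ascending slot order; (3) each spike's target list
// walked in list order, deliveries land in the ring buffer before step k+1;
// (4) per-step spike count appended to the workload trace.
//
// src_ptr/tgt/w/dsteps: CSR connectivity over slots (0-based).
// pulse_pool: slots eligible for the PRNG-driven pulse stimulus.

// [[Rcpp::export]]
List sim_core(NumericVector a, NumericVector b, NumericVector c, NumericVector d,
              NumericVector v0, NumericVector u0, LogicalVector active,
              IntegerVector src_ptr, IntegerVector tgt,
              NumericVector w, IntegerVector dsteps,
              int steps, int K_RB,
              NumericVector i_const,
              double pulse_amp, int pulse_n, double pulse_state,
              IntegerVector pulse_pool,
              bool fixed) {
  const int N = a.size();
  if ((K_RB & (K_RB - 1)) != 0 || K_RB < 2) stop("K_RB must be a power of two >= 2");
  int shift = 0;
  while ((1 << shift) != K_RB) ++shift;

  std::vector<int> spike_k, spike_n;
  IntegerVector workload(steps);
  int sat = 0;
  uint32_t prng = static_cast<uint32_t>(pulse_state);
  const int npool = pulse_pool.size();

  std::vector<double> pulse(N, 0.0);
  std::vector<int> pulsed; // touched slots, cleared each step
  std::vector<int> step_spikes;

  NumericVector v_out(N), u_out(N);

  if (fixed) {
    std::vector<int64_t> V(N), U(N), A(N), B(N), Cr(N), D(N), IC(N), W(w.size());
    for (int i = 0; i < N; ++i) {
      V[i] = fx::enc(v0[i]); U[i] = fx::enc(u0[i]);
      A[i] = fx::enc(a[i]);  B[i] = fx::enc(b[i]);
      Cr[i] = fx::enc(c[i]); D[i] = fx::enc(d[i]);
      IC[i] = fx::enc(i_const[i]);
    }
    for (R_xlen_t i = 0; i < w.size(); ++i) W[i] = fx::enc(w[i]);
    const int64_t PA = fx::enc(pulse_amp);

    std::vector<int64_t> rb_ex(static_cast<size_t>(K_RB) * N, 0);
    std::vector<int64_t> rb_in(static_cast<size_t>(K_RB) * N, 0);
    std::vector<int64_t> rb_kv(static_cast<size_t>(K_RB) * N, -1);

    for (int k = 0; k < steps; ++k) {
      // stimulus pulses for this step
      for (int j = 0; j < pulse_n && npool > 0; ++j) {
        prng = xns_next(prng);
        int idx = static_cast<int>((static_cast<double>(prng) / 4294967296.0) * npool);
        int slot = pulse_pool[idx];
        if (pulse[slot] == 0.0) pulsed.push_back(slot);
        pulse[slot] += 1.0; // pulse multiplicity
      }
      const int seg = k & (K_RB - 1);
      const int64_t stamp = static_cast<int64_t>(k) >> shift;
      step_spikes.clear();
      for (int n = 0; n < N; ++n) {
        if (!active[n]) continue;
        size_t idx = static_cast<size_t>(seg) * N + n;
        int64_t iex = 0, iinh = 0;
        if (rb_kv[idx] == stamp) { iex = rb_ex[idx]; iinh = rb_in[idx]; }
        int64_t iext = IC[n];
        if (pulse[n] != 0.0)
          for (int m = 0; m < static_cast<int>(pulse[n]); ++m)
            iext = fx::add(iext, PA, sat);
        bool spiked = false;
        euler_fx(V[n], U[n], A[n], B[n], Cr[n], D[n], iex, iinh, iext, sat, spiked);
        if (spiked) step_spikes.push_back(n);
      }
      // event-driven delivery: completes before step k + 1 begins
      for (int n : step_spikes) {
        spike_k.push_back(k);
        spike_n.push_back(n);
        for (int j = src_ptr[n]; j < src_ptr[n + 1]; ++j) {
          int64_t k2 = static_cast<int64_t>(k) + dsteps[j];
          size_t idx = static_cast<size_t>(k2 & (K_RB - 1)) * N + tgt[j];
          int64_t st2 = k2 >> shift;
          int64_t wr = W[j];
          if (rb_kv[idx] == st2) {
            if (wr >= 0) rb_ex[idx] = fx::add(rb_ex[idx], wr, sat);
            else         rb_in[idx] = fx::add(rb_in[idx], wr, sat);
          } else {
            rb_ex[idx] = wr >= 0 ? wr : 0;
            rb_in[idx] = wr < 0 ? wr : 0;
            rb_kv[idx] = st2;
          }
        }
      }
      workload[k] = static_cast<int>(step_spikes.size());
      for (int slot : pulsed) pulse[slot] = 0.0;
      pulsed.clear();
    }
    for (int i = 0; i < N; ++i) { v_out[i] = V[i] / fx::SCALE; u_out[i] = U[i] / fx::SCALE; }
  } else {
    std::vector<double> V(v0.begin(), v0.end()), U(u0.begin(), u0.end());
    std::vector<double> rb_ex(static_cast<size_t>(K_RB) * N, 0.0);
    std::vector<double> rb_in(static_cast<size_t>(K_RB) * N, 0.0);
    std::vector<int64_t> rb_kv(static_cast<size_t>(K_RB) * N, -1);

    for (int k = 0; k < steps; ++k) {
      for (int j = 0; j < pulse_n && npool > 0; ++j) {
        prng = xns_next(prng);
        int idx = static_cast<int>((static_cast<double>(prng) / 4294967296.0) * npool);
        int slot = pulse_pool[idx];
        if (pulse[slot] == 0.0) pulsed.push_back(slot);
        pulse[slot] += pulse_amp;
      }
      const int seg = k & (K_RB - 1);
      const int64_t stamp = static_cast<int64_t>(k) >> shift;
      step_spikes.clear();
      for (int n = 0; n < N; ++n) {
        if (!active[n]) continue;
        size_t idx = static_cast<size_t>(seg) * N + n;
        double iex = 0.0, iinh = 0.0;
        if (rb_kv[idx] == stamp) { iex = rb_ex[idx]; iinh = rb_in[idx]; }
        double iext = i_const[n] + pulse[n];
        bool spiked = false;
        euler_fl(V[n], U[n], a[n], b[n], c[n], d[n], iex, iinh, iext, spiked);
        if (spiked) step_spikes.push_back(n);
      }
      for (int n : step_spikes) {
        spike_k.push_back(k);
        spike_n.push_back(n);
        for (int j = src_ptr[n]; j < src_ptr[n + 1]; ++j) {
          int64_t k2 = static_cast<int64_t>(k) + dsteps[j];
          size_t idx = static_cast<size_t>(k2 & (K_RB - 1)) * N + tgt[j];
          int64_t st2 = k2 >> shift;
          if (rb_kv[idx] == st2) {
            if (w[j] >= 0) rb_ex[idx] += w[j];
            else           rb_in[idx] += w[j];
          } else {
            rb_ex[idx] = w[j] >= 0 ? w[j] : 0.0;
            rb_in[idx] = w[j] < 0 ? w[j] : 0.0;
            rb_kv[idx] = st2;
          }
        }
      }
      workload[k] = static_cast<int>(step_spikes.size());
      for (int slot : pulsed) pulse[slot] = 0.0;
      pulsed.clear();
    }
    for (int i = 0; i < N; ++i) { v_out[i] = V[i]; u_out[i] = U[i]; }
  }

  return List::create(_["spike_k"] = wrap(spike_k),
                      _["spike_neuron"] = wrap(spike_n),
                      _["workload"] = workload,
                      _["saturations"] = sat,
                      _["v"] = v_out, _["u"] = u_out);
}
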
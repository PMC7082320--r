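#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Arithmetic (floor) right shift; defined for negative values so that the
// behaviour matches the R-level fixed-point helpers exactly on every platform.
static inline int64_t sra(int64_t x, int k) {
  int64_t d = int64_t(1) << k;
  return (x >= 0) ? (x / d) : -((-x + d - 1) / d);
}

static inline int64_t clampi(int64_t x, int64_t lo, int64_t hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// One layer of the discrete-time LIF forward pass with the online per-synapse
// S-PSP accumulator, floating point.
//
// Per step t (unit step size):
//   p_j <- (1 - 1/tau_s) p_j + (1/tau_s) spike_j[t]        (synaptic trace)
//   u_i <- (1 - 1/tau_m) u_i + sum_j W(i,j) p_j            (membrane, = sum_j W q)
//   fire_i = (u_i >= nu); on fire u_i <- reset
//   q(i,j) <- (1 - 1/tau_m) q(i,j) + p_j
//   on fire: e(i,j) += q(i,j); q(i,j) <- 0
// [[Rcpp::export]]
List layer_forward_float(NumericMatrix W, IntegerMatrix pre_spikes,
                         double tau_m, double tau_s, double nu, double reset) {
  const int n_post = W.nrow(), n_pre = W.ncol(), T = pre_spikes.ncol();
  if (pre_spikes.nrow() != n_pre)
    stop("pre_spikes rows must equal the layer fan-in");
  const double as = 1.0 - 1.0 / tau_s, gs = 1.0 / tau_s;
  const double am = 1.0 - 1.0 / tau_m;

  std::vector<double> p(n_pre, 0.0), u(n_post, 0.0);
  NumericMatrix q(n_post, n_pre), e(n_post, n_pre);
  IntegerMatrix spikes(n_post, T);

  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n_pre; ++j)
      p[j] = as * p[j] + gs * double(pre_spikes(j, t));
    for (int i = 0; i < n_post; ++i) {
      double cur = 0.0;
      for (int j = 0; j < n_pre; ++j) cur += W(i, j) * p[j];
      u[i] = am * u[i] + cur;
    }
    for (int i = 0; i < n_post; ++i) {
      bool fired = (u[i] >= nu);
      if (fired) { u[i] = reset; spikes(i, t) = 1; }
      for (int j = 0; j < n_pre; ++j) {
        double qv = am * q(i, j) + p[j];
        if (fired) { e(i, j) += qv; qv = 0.0; }
        q(i, j) = qv;
      }
    }
  }
  return List::create(_["spikes"] = spikes, _["e"] = e);
}

// Fixed-point (hardware-emulation) counterpart. All state is kept as raw
// integers on the configured lattices; decays are truncating shifts
// (x <- x - (x >> k)), matching shift_decay(). Layout:
//   W      raw, signed, frac_w fractional bits (storage format)
//   p, q   raw, unsigned, frac_e fractional bits, saturating at e's max
//   e      raw, unsigned, frac_e fractional bits, saturating
//   u      raw, signed, frac_v fractional bits, saturating at v's range
// The weighted current is accumulated at full frac_w + frac_e precision and
// re-quantised to the membrane format by a truncating shift (wide hardware
// accumulator, narrow storage).
// [[Rcpp::export]]
List layer_forward_fixed(IntegerMatrix Wraw, IntegerMatrix pre_spikes,
                         int tm_pow, int ts_pow,
                         int frac_w, int frac_e, int frac_v,
                         double e_max, double v_min, double v_max,
                         double nu_raw, double reset_raw) {
  const int n_post = Wraw.nrow(), n_pre = Wraw.ncol(), T = pre_spikes.ncol();
  if (pre_spikes.nrow() != n_pre)
    stop("pre_spikes rows must equal the layer fan-in");
  const int64_t emax = (int64_t)e_max, vmin = (int64_t)v_min,
                vmax = (int64_t)v_max, nu_r = (int64_t)nu_raw,
                rst = (int64_t)reset_raw;
  const int64_t p_inject = sra(int64_t(1) << frac_e, ts_pow); // (1/tau_s)*1.0
  const int cur_shift = frac_w + frac_e - frac_v;

  std::vector<int64_t> p(n_pre, 0), u(n_post, 0);
  std::vector<int64_t> q((size_t)n_post * n_pre, 0);
  IntegerMatrix e(n_post, n_pre), spikes(n_post, T);

  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n_pre; ++j) {
      int64_t pv = p[j] - sra(p[j], ts_pow);
      if (pre_spikes(j, t)) pv += p_inject;
      p[j] = clampi(pv, 0, emax);
    }
    for (int i = 0; i < n_post; ++i) {
      int64_t acc = 0;
      for (int j = 0; j < n_pre; ++j) acc += (int64_t)Wraw(i, j) * p[j];
      int64_t cur = sra(acc, cur_shift);
      u[i] = clampi(u[i] - sra(u[i], tm_pow) + cur, vmin, vmax);
    }
    for (int i = 0; i < n_post; ++i) {
      bool fired = (u[i] >= nu_r);
      if (fired) { u[i] = rst; spikes(i, t) = 1; }
      int64_t* qi = &q[(size_t)i * n_pre];
      for (int j = 0; j < n_pre; ++j) {
        int64_t qv = clampi(qi[j] - sra(qi[j], tm_pow) + p[j], 0, emax);
        if (fired) {
          e(i, j) = (int)clampi((int64_t)e(i, j) + qv, 0, emax);
          qv = 0;
        }
        qi[j] = qv;
      }
    }
  }
  return List::create(_["spikes"] = spikes, _["e"] = e);
}
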
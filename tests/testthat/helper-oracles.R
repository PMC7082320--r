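# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths: the kernel oracle integrates the defining
# integral numerically, and the layer oracle steps the published recurrences
# one step at a time through the exported single-step operations.

# Numerical quadrature of the PSP integral: the exponential membrane leak
# integrated against the first-order synaptic impulse response
# exp(-x/tau_s)/tau_s over the accumulation window [0, min(s, t)].
psp_kernel_quadrature <- function(s, t, tau_m = 16, tau_s = 4) {
  if (s <= 0 || t <= 0) return(0)
  up <- min(s, t)
  stats::integrate(function(x) exp(-x / tau_m) * exp(-(t - x) / tau_s) / tau_s,
                   0, up, rel.tol = 1e-12)$value
}

# Step-through of one LIF layer with per-synapse S-PSP accumulation, driven
# entirely by the exported single-step ops (independent of the compiled
# trial kernel).
layer_forward_stepwise <- function(W, pre_spikes, params) {
  n_post <- nrow(W)
  n_pre <- ncol(W)
  T <- ncol(pre_spikes)
  st <- layer_state_init(n_post)
  syn <- lapply(seq_len(n_post), function(i) spsp_state_init(n_pre))
  spikes <- matrix(0L, n_post, T)
  for (t in seq_len(T)) {
    st <- lif_step(st, as.vector(W %*% pre_spikes[, t]), params)
    spikes[, t] <- st$fired
    for (i in seq_len(n_post)) {
      syn[[i]] <- spsp_online_step(syn[[i]], pre_spikes[, t], st$fired[i],
                                   params)
    }
  }
  list(spikes = spikes,
       e = do.call(rbind, lapply(syn, `[[`, "e")))
}

# Fixed-point layer step-through mirroring the documented integer datapath,
# written with plain floor arithmetic (independent of the compiled kernel).
layer_forward_fixed_stepwise <- function(Wraw, pre_spikes, params, formats) {
  sra <- function(x, k) floor(x / 2^k)
  tm_pow <- round(log2(params$tau_m))
  ts_pow <- round(log2(params$tau_s))
  fe <- formats$e$frac_bits
  emax <- formats$e$raw_max
  n_post <- nrow(Wraw)
  n_pre <- ncol(Wraw)
  T <- ncol(pre_spikes)
  p <- numeric(n_pre)
  u <- numeric(n_post)
  q <- matrix(0, n_post, n_pre)
  e <- matrix(0, n_post, n_pre)
  spikes <- matrix(0L, n_post, T)
  p_inject <- sra(2^fe, ts_pow)
  cur_shift <- formats$w$frac_bits + fe - formats$v$frac_bits
  nu_raw <- round(params$threshold * 2^formats$v$frac_bits)
  for (t in seq_len(T)) {
    p <- pmin(p - sra(p, ts_pow) + p_inject * pre_spikes[, t], emax)
    cur <- sra(as.vector(Wraw %*% p), cur_shift)
    u <- pmin(pmax(u - sra(u, tm_pow) + cur, formats$v$raw_min),
              formats$v$raw_max)
    fired <- u >= nu_raw
    u[fired] <- round(params$reset * 2^formats$v$frac_bits)
    spikes[fired, t] <- 1L
    q <- pmin(q - sra(q, tm_pow) + rep(p, each = n_post), emax)
    e[fired, ] <- pmin(e[fired, , drop = FALSE] + q[fired, , drop = FALSE],
                       emax)
    q[fired, ] <- 0
  }
  list(spikes = spikes, e = e)
}

# Random spike train with i.i.d. per-step firing probability.
random_train <- function(T, rate) as_spike_train(stats::rbinom(T, 1L, rate))
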
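#' One discrete LIF update step for a layer
#'
#' Advances a layer of LIF neurons by one forward-Euler step of size `dt`.
#' The synaptic current decays with factor `(1 - dt/tau_s)` and integrates
#' the weighted input spikes with gain `dt/tau_s`; the membrane potential
#' decays with factor `(1 - dt/tau_m)` and integrates the synaptic current,
#' \deqn{\alpha \leftarrow (1 - dt/\tau_s)\alpha + (dt/\tau_s)\,I,\qquad
#'       u \leftarrow (1 - dt/\tau_m)u + \alpha\,dt.}
#' Neurons whose potential reaches the threshold fire and are reset in the
#' same step. The membrane integrates the current without a `1/tau_m`
#' prefactor so that `u` equals the weight-sum of the per-synapse membrane
#' traces tracked by the online S-PSP accumulator, which ties firing counts
#' to the total post-synaptic potential (`o ~ a / nu`).
#'
#' @param state List with numeric vectors `u` (membrane potential), `alpha`
#'   (synaptic current) and `fired` (last step's spike indicator); use
#'   [layer_state_init()] for zeros.
#' @param weighted_input Per-neuron input current this step (typically
#'   `W %*% spikes`).
#' @param params [neuron_params()].
#' @param dt Step size; the default 1 matches the fixed-step simulator.
#' @return Updated state list; `fired` holds this step's 0/1 spike
#'   indicators.
#' @examples
#' st <- layer_state_init(3)
#' lif_step(st, c(5, 0, 0))$fired
#' @export
lif_step <- function(state, weighted_input, params = neuron_params(), dt = 1) {
  stopifnot(dt > 0)
  alpha <- (1 - dt / params$tau_s) * state$alpha +
    (dt / params$tau_s) * weighted_input
  u <- (1 - dt / params$tau_m) * state$u + alpha * dt
  fired <- u >= params$threshold
  u[fired] <- params$reset
  list(u = u, alpha = alpha, fired = as.integer(fired))
}

#' @rdname lif_step
#' @param n Number of neurons in the layer.
#' @export
layer_state_init <- function(n) {
  list(u = numeric(n), alpha = numeric(n), fired = integer(n))
}

#' Simulate a full forward pass with online S-PSP accumulation
#'
#' Runs the whole network for `T` steps, layer by layer from input to
#' output, while the online S-PSP accumulator tracks, for every synapse, the
#' accumulated spike-train level post-synaptic potential needed by the
#' spike-train level learning rules. Input-layer neurons are spike sources:
#' their train is given, not simulated.
#'
#' With `quantize = TRUE` the pass runs entirely in fixed-point integer
#' arithmetic on the configured storage formats (weights are snapped to the
#' weight lattice on entry), reproducing the shift-based hardware datapath
#' bit-for-bit.
#'
#' @param net [snn_network()].
#' @param input_spikes Binary matrix, `n_in x T` (rows = input neurons,
#'   columns = time steps), or a list of [spike_train()] objects.
#' @param quantize Run the fixed-point datapath instead of floating point.
#' @param formats Storage formats for the fixed-point path, as
#'   [fp_defaults()].
#' @return List with `spikes` (per-layer binary matrices, input first),
#'   `counts` (per-layer firing counts), `e` (per-connection S-PSP matrices,
#'   `e[[k]][i, j]` for the synapse from neuron `j` of layer `k` to neuron
#'   `i` of layer `k+1`), and in quantised mode `e_raw` (the raw lattice
#'   values). `counts[[length(counts)]]` are the output firing counts used
#'   for classification and for the rate-coded loss.
#' @examples
#' net <- snn_network(c(4, 3), seed = 1)
#' x <- matrix(rbinom(4 * 50, 1, 0.2), 4, 50)
#' fw <- forward_pass(net, x)
#' fw$counts
#' @export
forward_pass <- function(net, input_spikes, quantize = FALSE,
                         formats = fp_defaults()) {
  stopifnot(inherits(net, "snn_network"))
  if (is.list(input_spikes) && !is.matrix(input_spikes)) {
    stopifnot(all(vapply(input_spikes, inherits, logical(1), "spike_train")))
    input_spikes <- do.call(rbind, lapply(input_spikes, spike_indicator))
  }
  if (!is.matrix(input_spikes)) stop("input_spikes must be a matrix or a ",
                                     "list of spike_train objects",
                                     call. = FALSE)
  if (nrow(input_spikes) != net$layer_sizes[1L]) {
    stop("input_spikes has ", nrow(input_spikes), " rows but the network ",
         "expects ", net$layer_sizes[1L], " input neurons", call. = FALSE)
  }
  T <- ncol(input_spikes)
  if (T < 1L) stop("horizon T must be at least 1", call. = FALSE)
  p <- net$params
  if (quantize && !is_pow2_params(p)) {
    stop("fixed-point mode requires tau_m and tau_s to be powers of 2",
         call. = FALSE)
  }

  n_conn <- length(net$weights)
  spikes <- vector("list", n_conn + 1L)
  spikes[[1L]] <- input_spikes
  e <- vector("list", n_conn)
  e_raw <- if (quantize) vector("list", n_conn)

  storage.mode(spikes[[1L]]) <- "integer"
  for (k in seq_len(n_conn)) {
    if (quantize) {
      wq <- quantize(net$weights[[k]], formats$w)
      nu_raw <- round(p$threshold * 2^formats$v$frac_bits)
      reset_raw <- round(p$reset * 2^formats$v$frac_bits)
      res <- layer_forward_fixed(
        matrix(as.integer(wq$raw), nrow(wq$raw), ncol(wq$raw)),
        spikes[[k]],
        tm_pow = as.integer(round(log2(p$tau_m))),
        ts_pow = as.integer(round(log2(p$tau_s))),
        frac_w = formats$w$frac_bits, frac_e = formats$e$frac_bits,
        frac_v = formats$v$frac_bits,
        e_max = formats$e$raw_max, v_min = formats$v$raw_min,
        v_max = formats$v$raw_max,
        nu_raw = nu_raw, reset_raw = reset_raw)
      e_raw[[k]] <- res$e
      e[[k]] <- res$e * 2^-formats$e$frac_bits
    } else {
      res <- layer_forward_float(net$weights[[k]], spikes[[k]],
                                 tau_m = p$tau_m, tau_s = p$tau_s,
                                 nu = p$threshold, reset = p$reset)
      e[[k]] <- res$e
    }
    spikes[[k + 1L]] <- res$spikes
  }

  out <- list(spikes = spikes,
              counts = lapply(spikes, rowSums),
              e = e)
  if (quantize) out$e_raw <- e_raw
  out
}
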
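#' Rate-coded squared loss
#'
#' Loss of one example under rate coding: half the squared Euclidean
#' distance between the actual and desired output firing counts,
#' \eqn{E = \frac{1}{2}\lVert o - y \rVert_2^2}.
#'
#' @param o Actual firing counts of the output neurons.
#' @param y Desired firing counts (see [target_counts()]).
#' @return Scalar loss.
#' @examples
#' rate_loss(c(10, 3), c(8, 3))
#' @export
rate_loss <- function(o, y) {
  if (length(o) != length(y)) {
    stop("firing-count and target vectors must have equal length",
         call. = FALSE)
  }
  0.5 * sum((o - y)^2)
}

#' Output-layer error
#'
#' The error assigned to each output neuron under the rate-coded loss:
#' \eqn{\delta_i = (o_i - y_i)/\nu}, the count mismatch scaled by the firing
#' threshold (which converts counts back to the total-PSP scale on which
#' weights act).
#'
#' @inheritParams rate_loss
#' @param nu Firing threshold (> 0).
#' @return Numeric error vector, zero wherever the count matches its target.
#' @examples
#' output_error(c(10, 3), c(8, 3), nu = 1)
#' @export
output_error <- function(o, y, nu = 1) {
  stopifnot(nu > 0)
  if (length(o) != length(y)) {
    stop("firing-count and target vectors must have equal length",
         call. = FALSE)
  }
  (o - y) / nu
}

#' Hidden-layer error by direct feedback alignment
#'
#' Projects the output-layer error straight onto a hidden layer through its
#' fixed random feedback matrix: \eqn{\delta^k_i = \sum_l \delta^o_l b_{li}}.
#' No other layer's weights enter, so all hidden layers' errors can be
#' computed concurrently and the backward phase does not deepen with the
#' network.
#'
#' `method = "dense"` multiplies out the products; `method = "shift"`
#' (requires a power-of-2 feedback matrix) realises each product as a
#' sign-corrected arithmetic shift by the stored exponent, skipping masked
#' (zero) entries — the hardware datapath. Both methods accumulate terms in
#' the same order, and every shift product is exactly the corresponding
#' multiplication, so the two paths agree bit for bit, in floating point and
#' on fixed-point raw integers alike.
#'
#' @param delta_o Output-layer error vector (real, or raw fixed-point
#'   integers when emulating the quantised datapath).
#' @param B A [make_feedback()] matrix for this hidden layer.
#' @param method `"dense"` or `"shift"`.
#' @return Hidden-layer error vector, length `nrow(B$b)`.
#' @examples
#' B <- make_feedback(4, 3, seed = 1)
#' dfa_hidden_error(c(1, -2, 0.5), B)
#' @export
dfa_hidden_error <- function(delta_o, B, method = c("dense", "shift")) {
  method <- match.arg(method)
  stopifnot(inherits(B, "feedback_matrix"))
  if (length(delta_o) != ncol(B$b)) {
    stop("delta_o length must equal the output-layer width (",
         ncol(B$b), ")", call. = FALSE)
  }
  dmat <- matrix(delta_o, nrow(B$b), ncol(B$b), byrow = TRUE)
  prod <- if (method == "dense") {
    B$b * dmat
  } else {
    if (B$variant != "pow2") {
      stop("shift method requires a power-of-2 feedback matrix", call. = FALSE)
    }
    B$sign * (dmat * 2^B$m)       # sign-corrected arithmetic shift; 0 masked
  }
  rowSums(prod)
}

#' Spike-train level weight update
#'
#' The weight update of the spike-train level learning rule:
#' \eqn{\Delta w_{ij} = \eta\, \delta_i\, e_{i|j}}, the layer error scaled by
#' each synapse's accumulated S-PSP (the sensitivity of the neuron's total
#' PSP to that weight). The caller applies `w <- w - delta_w` (gradient
#' descent on the rate-coded loss).
#'
#' @param delta Error vector of the post-synaptic layer (length n_post).
#' @param e S-PSP matrix of the connection (n_post x n_pre).
#' @param eta Learning rate (> 0).
#' @return Matrix of weight deltas, same shape as `e`.
#' @examples
#' stdfa_weight_update(c(1, -1), matrix(1:6 / 10, 2, 3), eta = 0.1)
#' @export
stdfa_weight_update <- function(delta, e, eta) {
  stopifnot(eta > 0, is.matrix(e))
  if (length(delta) != nrow(e)) {
    stop("delta length must equal nrow(e)", call. = FALSE)
  }
  eta * delta * e    # delta recycles down columns: row i scaled by delta[i]
}

#' Hidden-layer error by symmetric-weight backpropagation (baseline)
#'
#' Comparison baseline that propagates the next layer's error backwards
#' through the transposed forward weights, with the S-PSP sensitivity
#' approximated per-synapse by the average contribution per post-synaptic
#' spike:
#' \deqn{\delta^k_i = \frac{1}{\nu} \sum_l \delta^{k+1}_l\, w^{k+1}_{li}\,
#'   \frac{e^{k+1}_{l|i}}{o_i},}
#' the ratio defined as 0 for silent neurons (`o_i = 0`). This keeps the
#' simplified spike-train level form of the forward rule (the second-order
#' dependence of S-PSPs on the post-synaptic train is dropped) and is
#' provided only to compare direct feedback against weight-transport
#' backpropagation; it is not a faithful reproduction of any published
#' micro-level gradient.
#'
#' @param delta_next Error vector of layer k+1 (length n_next).
#' @param W_next Forward weight matrix of layer k+1 (n_next x n_k).
#' @param e_next S-PSP matrix of the k -> k+1 connection (n_next x n_k).
#' @param o Firing counts of layer k's neurons (length n_k).
#' @param nu Firing threshold.
#' @return Error vector for layer k (length n_k).
#' @export
bp_hidden_error <- function(delta_next, W_next, e_next, o, nu = 1) {
  stopifnot(is.matrix(W_next), is.matrix(e_next),
            all(dim(W_next) == dim(e_next)), nu > 0)
  if (length(delta_next) != nrow(W_next) || length(o) != ncol(W_next)) {
    stop("shape mismatch between delta_next, W_next and o", call. = FALSE)
  }
  contrib <- colSums(delta_next * W_next * e_next)   # sum over l per column i
  ratio <- ifelse(o == 0, 0, contrib / o)
  ratio / nu
}

#' Desired firing counts for a class label
#'
#' Deterministic rate-coded target: the correct class's output neuron is
#' asked to fire `hi` times over the trial, every other output neuron `lo`
#' times.
#'
#' @param label Class label, 1-based integer in `1..n_out`.
#' @param n_out Number of output neurons (classes).
#' @param hi,lo Desired counts for the correct / incorrect neurons
#'   (non-negative, `hi > lo`).
#' @return Integer vector of length `n_out`.
#' @examples
#' target_counts(2, 3)
#' @export
target_counts <- function(label, n_out, hi = 35, lo = 5) {
  stopifnot(length(label) == 1L, label >= 1, label <= n_out,
            hi > lo, lo >= 0)
  y <- rep(lo, n_out)
  y[label] <- hi
  as.numeric(y)
}

#' Training configuration
#'
#' Collects the training hyperparameters. `eta` is the learning rate of the
#' weight update; `hi`/`lo` parameterise [target_counts()]; `quantize`
#' switches the whole pipeline (forward pass, error feedback, weight
#' storage) to the fixed-point datapath with the formats in `formats`.
#'
#' @param eta Learning rate (> 0).
#' @param epochs Maximum number of passes over the training set.
#' @param seed Integer seed for all stochastic elements of a run.
#' @param hi,lo Target firing counts for correct/incorrect output neurons.
#' @param quantize Use fixed-point emulation.
#' @param formats Fixed-point storage formats ([fp_defaults()]).
#' @param stop_accuracy Optional early-stopping threshold: training stops
#'   once the epoch's training accuracy (percent) reaches this value.
#' @param shuffle Shuffle example order each epoch (default `FALSE`:
#'   fixed-order online updates).
#' @return A `train_config` list.
#' @export
train_config <- function(eta = 2e-5, epochs = 100, seed = 1,
                         hi = 35, lo = 5, quantize = FALSE,
                         formats = fp_defaults(), stop_accuracy = NULL,
                         shuffle = FALSE) {
  stopifnot(eta > 0, epochs >= 1, hi > lo, lo >= 0)
  structure(list(eta = eta, epochs = as.integer(epochs),
                 seed = as.integer(seed), hi = hi, lo = lo,
                 quantize = isTRUE(quantize), formats = formats,
                 stop_accuracy = stop_accuracy, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Train on a single example
#'
#' One online training step: a full forward pass over all `T` steps with
#' online S-PSP accumulation, then the output error, then — from that same
#' output error — the error of every hidden layer at once (direct feedback;
#' no hidden layer sees another's update), and finally the weight updates,
#' applied before the next example.
#'
#' Rules: `"stdfa"` projects the output error through the real-valued
#' feedback matrices; `"stdfa2"` through power-of-2 matrices using the
#' shift datapath; `"bp"` backpropagates through the transposed forward
#' weights ([bp_hidden_error()], baseline); `"frozen"` performs the forward
#' pass only (control). The output layer always trains on its own error
#' \eqn{\delta^o}.
#'
#' @param net [snn_network()] (its `feedback_variant` should match the rule).
#' @param input_spikes Binary `n_in x T` matrix (or list of
#'   [spike_train()]).
#' @param label 1-based class label.
#' @param cfg [train_config()].
#' @param rule One of `"stdfa"`, `"stdfa2"`, `"bp"`, `"frozen"`.
#' @return List with the updated `net`, the example `loss`, the output
#'   `counts`, and `predicted` (argmax of output counts, ties to the lowest
#'   index).
#' @export
train_example <- function(net, input_spikes, label, cfg = train_config(),
                          rule = c("stdfa", "stdfa2", "bp", "frozen")) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "snn_network"), inherits(cfg, "train_config"))
  fw <- forward_pass(net, input_spikes, quantize = cfg$quantize,
                     formats = cfg$formats)
  n_layers <- length(net$weights)
  n_out <- net$layer_sizes[length(net$layer_sizes)]
  o <- fw$counts[[n_layers + 1L]]
  y <- target_counts(label, n_out, hi = cfg$hi, lo = cfg$lo)
  loss <- rate_loss(o, y)
  predicted <- which.max(o)

  if (rule != "frozen" && loss > 0) {
    nu <- net$params$threshold
    delta_o <- output_error(o, y, nu)
    deltas <- vector("list", n_layers)
    deltas[[n_layers]] <- delta_o
    if (rule == "bp") {
      for (k in rev(seq_len(n_layers - 1L))) {
        deltas[[k]] <- bp_hidden_error(deltas[[k + 1L]],
                                       net$weights[[k + 1L]],
                                       fw$e[[k + 1L]],
                                       fw$counts[[k + 1L]], nu)
      }
    } else {
      method <- if (rule == "stdfa2") "shift" else "dense"
      for (k in seq_len(n_layers - 1L)) {   # each from delta_o only
        deltas[[k]] <- dfa_hidden_error(delta_o, net$feedback[[k]], method)
      }
    }
    for (k in seq_len(n_layers)) {
      dw <- stdfa_weight_update(deltas[[k]], fw$e[[k]], cfg$eta)
      if (cfg$quantize) {
        # delta-w snaps to the weight lattice; weights live on it already
        dw <- fp_real(quantize(dw, cfg$formats$w))
        w <- net$weights[[k]] - dw
        net$weights[[k]] <- fp_real(quantize(w, cfg$formats$w))
      } else {
        net$weights[[k]] <- net$weights[[k]] - dw
      }
    }
  }
  list(net = net, loss = loss, counts = o, predicted = predicted)
}
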
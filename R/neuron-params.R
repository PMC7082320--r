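#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the time constants and firing threshold of the discrete-time
#' LIF/SRM neuron model used throughout the package. Time is discretised with
#' a unit step, so `tau_m` and `tau_s` are expressed in time steps. The leak
#' resistance is fixed to 1 (it is absorbed into the synaptic weights).
#'
#' The membrane time constant must exceed the synaptic time constant
#' (`tau_m > tau_s > 0`): the closed-form PSP kernel normalises by
#' `1 - tau_s/tau_m`, which degenerates when the two are equal. In
#' hardware-emulation (fixed-point) mode both constants must be integer powers
#' of 2 so that the per-step decays become arithmetic shifts.
#'
#' @param tau_m Membrane time constant, in time steps. Default 16.
#' @param tau_s Synaptic time constant, in time steps. Default 4.
#' @param threshold Firing threshold \eqn{\nu} of the membrane potential.
#'   Default 1.
#' @param reset Membrane potential value restored when a neuron fires.
#'   Default 0.
#'
#' @return An object of class `neuron_params`: a list with elements `tau_m`,
#'   `tau_s`, `threshold`, `reset`.
#' @examples
#' p <- neuron_params()
#' p$tau_m
#' @export
neuron_params <- function(tau_m = 16, tau_s = 4, threshold = 1, reset = 0) {
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L,
            is.numeric(tau_s), length(tau_s) == 1L,
            is.numeric(threshold), length(threshold) == 1L,
            is.numeric(reset), length(reset) == 1L)
  if (!(tau_m > tau_s && tau_s > 0)) {
    stop("invalid neuron parameters: need tau_m > tau_s > 0 ",
         "(got tau_m = ", tau_m, ", tau_s = ", tau_s, ")", call. = FALSE)
  }
  if (threshold <= 0) {
    stop("invalid neuron parameters: threshold must be > 0", call. = FALSE)
  }
  structure(
    list(tau_m = tau_m, tau_s = tau_s, threshold = threshold, reset = reset),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> tau_m = %g, tau_s = %g, threshold = %g, reset = %g\n",
              x$tau_m, x$tau_s, x$threshold, x$reset))
  invisible(x)
}

# TRUE when both time constants are integer powers of 2 (required for the
# shift-based hardware-emulation path).
is_pow2_params <- function(params) {
  is_pow2 <- function(x) x > 0 && x == 2^round(log2(x))
  is_pow2(params$tau_m) && is_pow2(params$tau_s)
}

#' Post-synaptic potential kernel
#'
#' Closed-form, normalised time course \eqn{\epsilon(s, t)} of the membrane
#' response of a post-synaptic neuron to a single pre-synaptic spike under the
#' spike response model with a first-order synapse:
#' \deqn{\epsilon(s,t) = \frac{e^{-\max(t-s,0)/\tau_s}}{1-\tau_s/\tau_m}
#'   \left[e^{-\min(s,t)/\tau_m} - e^{-\min(s,t)/\tau_s}\right] H(s) H(t),}
#' where `t` is the time elapsed since the pre-synaptic spike, `s` the time
#' elapsed since the post-synaptic neuron's last firing (its PSP accumulation
#' restarts there), and `H` the Heaviside step function. Equivalently,
#' \eqn{\epsilon} is the integral of the exponential membrane leak against the
#' synaptic impulse response \eqn{e^{-x/\tau_s}/\tau_s} over the accumulation
#' window.
#'
#' Negative arguments are allowed and yield 0 (causality); `s = Inf` encodes
#' "no previous post-synaptic spike", in which case the accumulation window is
#' the whole interval since the pre-synaptic spike.
#'
#' @param s Time since the last post-synaptic spike (vectorised).
#' @param t Time since the pre-synaptic spike (vectorised).
#' @param params A [neuron_params()] object.
#' @return Kernel values, non-negative, recycled to the common length of `s`
#'   and `t`.
#' @examples
#' psp_kernel(8, 3, neuron_params())
#' psp_kernel(-1, 5, neuron_params())  # 0: nothing accumulates before a reset
#' @export
psp_kernel <- function(s, t, params = neuron_params()) {
  stopifnot(inherits(params, "neuron_params"))
  tau_m <- params$tau_m
  tau_s <- params$tau_s
  n <- max(length(s), length(t))
  s <- rep_len(s, n)
  t <- rep_len(t, n)
  m <- pmin(s, t)
  lead <- exp(-pmax(t - s, 0) / tau_s)
  # s = Inf gives lead = exp(-0) after pmax(-Inf, 0); guard the NaN from t - Inf
  lead[is.infinite(s) & s > 0] <- exp(-0)
  val <- lead / (1 - tau_s / tau_m) * (exp(-m / tau_m) - exp(-m / tau_s))
  val[s < 0 | t < 0] <- 0
  val
}
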
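#' Spike-train level post-synaptic potential, event-based definition
#'
#' Computes the S-PSP \eqn{e_{i|j}}: the total (weight-normalised) membrane
#' contribution that the spike train of pre-synaptic neuron `j` makes to
#' post-synaptic neuron `i`, evaluated at `i`'s firing times,
#' \deqn{e_{i|j} = \sum_{t_i^{(f)}} \sum_{t_j^{(f)}}
#'   \epsilon\!\left(t_i^{(f)} - \hat t_i^{(f)},\; t_i^{(f)} - t_j^{(f)}\right),}
#' where \eqn{\hat t_i^{(f)}} is the post-neuron's previous firing time.
#' Before the first post-synaptic spike the accumulation window extends back
#' to the trial start (\eqn{\hat t_i = -\infty}).
#'
#' Two evaluation modes are provided. `"discrete"` evaluates the double sum
#' over the same fixed-step recurrences used by the online accumulator
#' ([spsp_online_step()]), so in exact arithmetic it equals the accumulator's
#' final value; it is the reference against which the online path is checked.
#' `"continuous"` uses the closed-form kernel [psp_kernel()]; the discrete
#' value converges to it (first order in \eqn{1/\tau_s}) as time constants and
#' spike spacings are scaled up together.
#'
#' This event-based form is a specification/testing oracle: the production
#' path accumulates the same quantity online during the forward pass.
#'
#' @param pre,post [spike_train()] objects sharing one horizon.
#' @param params [neuron_params()].
#' @param mode `"discrete"` (default) or `"continuous"`.
#' @return The scalar S-PSP value (non-negative).
#' @examples
#' p <- neuron_params()
#' spsp_direct(spike_train(2, 20), spike_train(10, 20), p)
#' @export
spsp_direct <- function(pre, post, params = neuron_params(),
                        mode = c("discrete", "continuous")) {
  stopifnot(inherits(pre, "spike_train"), inherits(post, "spike_train"),
            inherits(params, "neuron_params"))
  mode <- match.arg(mode)
  if (pre$horizon != post$horizon) {
    stop("pre and post spike trains must share the same horizon", call. = FALSE)
  }
  if (!length(pre$times) || !length(post$times)) return(0)

  prev_fire <- c(-Inf, post$times[-length(post$times)])
  e <- 0
  for (k in seq_along(post$times)) {
    tf <- post$times[k]
    s <- tf - prev_fire[k]                  # Inf before the first post spike
    t <- tf - pre$times                     # one entry per pre spike
    e <- e + if (mode == "continuous") {
      sum(psp_kernel(s, t, params))
    } else {
      sum(vapply(t, spsp_kernel_discrete, numeric(1), s = s, params = params))
    }
  }
  e
}

# Discrete-time counterpart of psp_kernel: the value that a single pre spike
# (t steps ago) contributes to q at a post firing whose accumulation window
# opened s steps ago, under the fixed-step recurrences
#   p[n+1] = (1 - 1/tau_s) p[n] + (1/tau_s) spike[n+1]
#   q[n+1] = (1 - 1/tau_m) q[n] + p[n+1].
# Summing the pre spike's p tail through the window gives
#   (1/tau_s) * sum_{u=0}^{min(s-1, t)} (1-1/tau_m)^u (1-1/tau_s)^(t-u),
# with s = Inf meaning "window open since trial start".
spsp_kernel_discrete <- function(s, t, params) {
  if (t < 0 || s <= 0) return(0)
  a <- 1 - 1 / params$tau_m
  b <- 1 - 1 / params$tau_s
  u_max <- min(s - 1, t)
  u <- 0:u_max
  sum(a^u * b^(t - u)) / params$tau_s
}

#' Online S-PSP accumulator, one time step
#'
#' Advances the per-synapse traces of the online S-PSP computation by one
#' fixed time step (first-order Euler discretisation of the synaptic and
#' membrane trace dynamics):
#' \deqn{p \leftarrow (1 - 1/\tau_s)\,p + (1/\tau_s)\,\mathrm{pre},\qquad
#'       q \leftarrow (1 - 1/\tau_m)\,q + p,}
#' then, if the post-synaptic neuron fired this step,
#' \eqn{e \leftarrow e + q} and \eqn{q \leftarrow 0}. The update order —
#' pre-spike injection into `p`, then `q`, then post-fire capture — matches
#' the hardware dataflow and resolves the one-step ambiguity of the
#' recurrence; a pre and post spike in the same step therefore contribute to
#' `e` in that step.
#'
#' All three traces vectorise over synapses (recycling rules apply), so one
#' call can advance a whole row of the synapse state.
#'
#' @param state List with numeric fields `p`, `q`, `e` (use
#'   [spsp_state_init()] for zeros).
#' @param pre_fired,post_fired 0/1 spike indicators for this step.
#' @param params [neuron_params()].
#' @return The updated state list.
#' @examples
#' st <- spsp_state_init(1)
#' spsp_online_step(st, pre_fired = 1, post_fired = 0)
#' @export
spsp_online_step <- function(state, pre_fired, post_fired,
                             params = neuron_params()) {
  p <- (1 - 1 / params$tau_s) * state$p + (1 / params$tau_s) * pre_fired
  q <- (1 - 1 / params$tau_m) * state$q + p
  e <- state$e
  fired <- as.logical(post_fired)
  if (length(fired) == 1L && length(q) > 1L) fired <- rep(fired, length(q))
  e <- e + ifelse(fired, q, 0)
  q[fired] <- 0
  list(p = p, q = q, e = e)
}

#' @rdname spsp_online_step
#' @param n Number of synapses to track.
#' @export
spsp_state_init <- function(n = 1L) {
  z <- numeric(n)
  list(p = z, q = z, e = z)
}

#' Run the online S-PSP accumulator over a whole trial
#'
#' Steps [spsp_online_step()] across the full horizon of a pre/post spike
#' train pair and returns the accumulated S-PSP. This is the reference R
#' implementation of the production online path; `spsp_direct()` is the
#' independent event-based evaluation of the same quantity.
#'
#' @inheritParams spsp_direct
#' @return Final accumulated `e` (scalar).
#' @export
spsp_online_run <- function(pre, post, params = neuron_params()) {
  stopifnot(inherits(pre, "spike_train"), inherits(post, "spike_train"))
  if (pre$horizon != post$horizon) {
    stop("pre and post spike trains must share the same horizon", call. = FALSE)
  }
  pre_ind <- spike_indicator(pre)
  post_ind <- spike_indicator(post)
  st <- spsp_state_init(1L)
  for (t in seq_len(pre$horizon)) {
    st <- spsp_online_step(st, pre_ind[t], post_ind[t], params)
  }
  st$e
}
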
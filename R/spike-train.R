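#' Spike train of a single neuron
#'
#' An ordered record of the discrete time steps (0-based, `0 .. horizon - 1`)
#' at which one neuron fired during a trial. A neuron can fire at most once
#' per step, so times are strictly increasing integers.
#'
#' @param times Integer vector of firing time steps, non-negative, strictly
#'   increasing, all `< horizon`.
#' @param horizon Trial length in time steps (positive integer).
#' @return An object of class `spike_train` with fields `times` and `horizon`.
#' @examples
#' spike_train(c(2, 10, 11), horizon = 100)
#' @export
spike_train <- function(times, horizon) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 1)
  times <- as.integer(times)
  if (length(times)) {
    if (any(times < 0L) || any(times >= horizon)) {
      stop("spike times must lie in [0, horizon)", call. = FALSE)
    }
    if (any(diff(times) <= 0L)) {
      stop("spike times must be strictly increasing (one spike per step)",
           call. = FALSE)
    }
  }
  structure(list(times = times, horizon = as.integer(horizon)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %d steps\n",
              length(x$times), x$horizon))
  if (length(x$times)) cat(" times:", paste(utils::head(x$times, 20L), collapse = " "),
                           if (length(x$times) > 20L) "...\n" else "\n")
  invisible(x)
}

#' @rdname spike_train
#' @param x For `as_spike_train()`, a 0/1 indicator vector (one entry per
#'   step); for `spike_indicator()`, a `spike_train`.
#' @export
as_spike_train <- function(x) {
  stopifnot(is.numeric(x) || is.logical(x))
  spike_train(which(as.logical(x)) - 1L, horizon = length(x))
}

#' @rdname spike_train
#' @export
spike_indicator <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  ind <- integer(x$horizon)
  ind[x$times + 1L] <- 1L
  ind
}

#' Convert between spike matrices and sparse (neuron, time) tables
#'
#' A population of spike trains over a common horizon is represented as a
#' binary matrix with one row per neuron and one column per time step
#' (column `t` holds the spikes of 0-based time step `t - 1`). These helpers
#' convert to and from the portable long form: a data frame with columns
#' `neuron` (1-based index) and `time` (0-based step), which serialises
#' naturally to CSV.
#'
#' @param spikes Binary matrix, neurons x time steps.
#' @return `spikes_to_table()`: a data.frame with columns `neuron`, `time`,
#'   ordered by time then neuron. `table_to_spikes()`: the binary matrix.
#' @examples
#' m <- matrix(0L, 2, 5); m[1, 3] <- 1L
#' spikes_to_table(m)
#' @export
spikes_to_table <- function(spikes) {
  stopifnot(is.matrix(spikes))
  idx <- which(spikes != 0, arr.ind = TRUE)
  out <- data.frame(neuron = as.integer(idx[, 1L]),
                    time = as.integer(idx[, 2L]) - 1L)
  out[order(out$time, out$neuron), , drop = FALSE]
}

#' @rdname spikes_to_table
#' @param tab Data frame with columns `neuron` and `time`.
#' @param n_neurons,horizon Dimensions of the reconstructed matrix.
#' @export
table_to_spikes <- function(tab, n_neurons, horizon) {
  stopifnot(all(c("neuron", "time") %in% names(tab)))
  m <- matrix(0L, n_neurons, horizon)
  if (nrow(tab)) {
    if (any(tab$neuron < 1L | tab$neuron > n_neurons) ||
        any(tab$time < 0L | tab$time >= horizon)) {
      stop("spike table entries outside the stated dimensions", call. = FALSE)
    }
    m[cbind(tab$neuron, tab$time + 1L)] <- 1L
  }
  m
}
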
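#' Poisson rate encoding of intensities
#'
#' Encodes a vector of intensities in `[0, 1]` (e.g. normalised pixel
#' values) into spike trains by Poisson sampling: in every time step each
#' input neuron fires independently with probability
#' `intensity * peak_rate` (per-step Bernoulli sampling at unit step size).
#'
#' @param intensities Numeric vector in `[0, 1]`, one entry per input
#'   neuron.
#' @param horizon Number of time steps `T`.
#' @param peak_rate Per-step firing probability of a full-intensity input.
#' @param seed Optional integer; reproducible without disturbing the
#'   caller's RNG stream.
#' @return Binary matrix `length(intensities) x horizon`.
#' @examples
#' s <- poisson_encode(c(0, 0.5, 1), horizon = 100, seed = 1)
#' rowMeans(s)
#' @export
poisson_encode <- function(intensities, horizon, peak_rate = 0.35,
                           seed = NULL) {
  if (any(intensities < 0 | intensities > 1)) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(horizon >= 1, peak_rate > 0, peak_rate <= 1)
  n <- length(intensities)
  with_seed(seed, {
    m <- matrix(stats::rbinom(n * horizon, 1L, rep(intensities * peak_rate,
                                                   times = horizon)),
                n, horizon)
    m
  })
}

#' Center crop of an image
#'
#' Extracts the centred `size x size` window of an image matrix (the
#' even-margin convention: the top-left offset is `floor((dim - size)/2)`),
#' e.g. reducing 28 x 28 inputs to the central 14 x 14 pixels to cut input
#' resolution 4-fold.
#'
#' @param image Numeric matrix `H x W`.
#' @param size Side length of the square crop (`<= min(H, W)`).
#' @return The `size x size` submatrix.
#' @examples
#' center_crop(matrix(1:16, 4, 4), 2)
#' @export
center_crop <- function(image, size = 14) {
  stopifnot(is.matrix(image))
  if (size > min(dim(image))) {
    stop("crop size exceeds the image dimensions", call. = FALSE)
  }
  r0 <- floor((nrow(image) - size) / 2)
  c0 <- floor((ncol(image) - size) / 2)
  image[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
}

#' Specification of the synthetic rate-coded classification task
#'
#' Describes a multi-class task with known ground truth: each class has a
#' template subset of the input neurons; an example of class `c` fires its
#' template neurons at `peak_rate` and all other inputs at `base_rate`
#' (per-step Bernoulli). `overlap` is the fraction of each template shared
#' between all classes, controlling class separation. The generator exposes
#' the templates so tests can bound achievable accuracy independently of any
#' learner.
#'
#' @param n_classes Number of classes.
#' @param n_inputs Number of input neurons.
#' @param horizon Trial length `T` in time steps.
#' @param base_rate,peak_rate Per-step firing probabilities off/on template
#'   (`0 <= base_rate < peak_rate <= 1`).
#' @param overlap Fraction of each class template shared with the other
#'   classes (`0 <= overlap < 1`).
#' @param n_per_class Examples generated per class.
#' @param seed Integer seed; the dataset is a pure function of this spec.
#' @return A `rate_task_spec` list.
#' @export
rate_task_spec <- function(n_classes = 3, n_inputs = 20, horizon = 100,
                           base_rate = 0.05, peak_rate = 0.35,
                           overlap = 0.2, n_per_class = 20, seed = 1) {
  stopifnot(n_classes >= 2, n_inputs >= n_classes,
            base_rate >= 0, base_rate < peak_rate, peak_rate <= 1,
            overlap >= 0, overlap < 1, n_per_class >= 1, horizon >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_inputs = as.integer(n_inputs),
                 horizon = as.integer(horizon),
                 base_rate = base_rate, peak_rate = peak_rate,
                 overlap = overlap, n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "rate_task_spec")
}

#' Generate a labelled synthetic rate-coded dataset
#'
#' Realises a [rate_task_spec()]: builds the class templates (a shared block
#' of `round(overlap * template_size)` inputs common to all classes plus
#' disjoint private blocks), then Poisson-samples `n_per_class` spike-train
#' examples per class. Deterministic given the spec (which includes the
#' seed).
#'
#' @param spec A [rate_task_spec()].
#' @return List with `examples` (list of binary `n_inputs x horizon`
#'   matrices), `labels` (1-based integer vector), `templates` (list of
#'   per-class logical vectors over inputs — the ground truth), and `spec`.
#' @examples
#' task <- make_rate_task(rate_task_spec(n_per_class = 2))
#' table(task$labels)
#' @export
make_rate_task <- function(spec) {
  stopifnot(inherits(spec, "rate_task_spec"))
  m <- spec$n_inputs %/% spec$n_classes        # template size per class
  n_shared <- round(spec$overlap * m)
  n_private <- m - n_shared
  if (n_shared + n_private * spec$n_classes > spec$n_inputs) {
    stop("inconsistent task spec: templates do not fit into n_inputs",
         call. = FALSE)
  }
  shared <- seq_len(n_shared)
  templates <- lapply(seq_len(spec$n_classes), function(c) {
    priv <- n_shared + (c - 1L) * n_private + seq_len(n_private)
    tpl <- logical(spec$n_inputs)
    tpl[c(shared, priv)] <- TRUE
    tpl
  })

  n_total <- spec$n_classes * spec$n_per_class
  labels <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
  examples <- with_seed(spec$seed, {
    lapply(labels, function(c) {
      rate <- ifelse(templates[[c]], spec$peak_rate, spec$base_rate)
      matrix(stats::rbinom(spec$n_inputs * spec$horizon, 1L,
                           rep(rate, times = spec$horizon)),
             spec$n_inputs, spec$horizon)
    })
  })
  list(examples = examples, labels = labels, templates = templates,
       spec = spec)
}

#' Template-matching oracle classifier
#'
#' Classifies an example by counting spikes on each class template and
#' taking the argmax (ties to the lowest class index). With disjoint
#' templates and zero background rate this classifier is exact; it bounds
#' the accuracy achievable on a generated dataset independently of any
#' trained network.
#'
#' @param example Binary `n_inputs x horizon` spike matrix.
#' @param templates Per-class logical template vectors (as produced by
#'   [make_rate_task()]).
#' @return Predicted 1-based class label.
#' @export
template_classify <- function(example, templates) {
  counts <- rowSums(example)
  scores <- vapply(templates, function(tpl) sum(counts[tpl]) / sum(tpl),
                   numeric(1))
  which.max(scores)
}
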
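#' Multi-layer feed-forward spiking network
#'
#' Builds a fully-connected feed-forward LIF network. Input-layer neurons are
#' pure spike sources (no dynamics); every subsequent layer is a population
#' of LIF neurons. Each hidden layer carries a fixed random feedback matrix
#' that projects the output-layer error directly onto it during training —
#' the direct-feedback-alignment pathway that replaces layer-by-layer
#' backpropagation through transposed weights.
#'
#' Hidden-layer weights are initialised i.i.d. uniform on `(-a, a)` with
#' `a = init_scale / sqrt(fan_in)`; the default `init_scale` is chosen so a
#' layer driven by moderate input rates produces membrane fluctuations of the
#' order of the firing threshold. Output-layer weights are initialised
#' uniform on `(0, output_init_scale / sqrt(fan_in))` — positive, so every
#' output neuron fires at the start of training. This matters for rate-coded
#' learning: the S-PSP of a neuron that never fires is identically zero, so
#' a silent output neuron receives no weight update and can never recover;
#' an initially active readout avoids that degenerate fixed point
#' (documented in the methods vignette).
#'
#' @param layer_sizes Integer vector `c(n_in, hidden..., n_out)`, length
#'   >= 2.
#' @param params [neuron_params()] shared by all LIF layers.
#' @param feedback_variant `"real"` (ST-DFA) or `"pow2"` (ST-DFA-2) feedback
#'   matrices; see [make_feedback()].
#' @param value_set Power-of-2 value set passed to [make_feedback()].
#' @param init_scale Hidden-layer weight-initialisation scale factor (see
#'   Details).
#' @param output_init_scale Output-layer (positive) initialisation scale
#'   factor (see Details).
#' @param seed Optional integer seed making weights and feedback matrices
#'   reproducible.
#' @return An object of class `snn_network`: list with `layer_sizes`,
#'   `weights` (list of matrices, `weights[[k]]` of shape
#'   `layer_sizes[k+1] x layer_sizes[k]`), `params`, `feedback` (one
#'   `feedback_matrix` per hidden layer), `init_scale`, `seed`.
#' @examples
#' net <- snn_network(c(20, 30, 3), seed = 1)
#' dim(net$weights[[1]])
#' @export
snn_network <- function(layer_sizes, params = neuron_params(),
                        feedback_variant = c("real", "pow2"),
                        value_set = c(-4, -2, -1, 0, 1, 2, 4),
                        init_scale = 2.5, output_init_scale = 0.66,
                        seed = NULL) {
  feedback_variant <- match.arg(feedback_variant)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must list at least an input and an output layer, ",
         "all sizes >= 1", call. = FALSE)
  }
  stopifnot(inherits(params, "neuron_params"))
  n_conn <- length(layer_sizes) - 1L
  n_out <- layer_sizes[length(layer_sizes)]

  build <- function() {
    weights <- vector("list", n_conn)
    for (k in seq_len(n_conn)) {
      fan_in <- layer_sizes[k]
      n_post <- layer_sizes[k + 1L]
      weights[[k]] <- if (k == n_conn) {
        a <- output_init_scale / sqrt(fan_in)
        matrix(stats::runif(n_post * fan_in, 0, a), n_post, fan_in)
      } else {
        a <- init_scale / sqrt(fan_in)
        matrix(stats::runif(n_post * fan_in, -a, a), n_post, fan_in)
      }
    }
    feedback <- vector("list", max(n_conn - 1L, 0L))
    for (k in seq_len(n_conn - 1L)) {   # hidden layers only
      feedback[[k]] <- make_feedback(layer_sizes[k + 1L], n_out,
                                     variant = feedback_variant,
                                     value_set = value_set)
    }
    list(weights = weights, feedback = feedback)
  }
  wb <- with_seed(seed, build())

  structure(list(layer_sizes = layer_sizes,
                 weights = wb$weights,
                 feedback = wb$feedback,
                 params = params,
                 feedback_variant = feedback_variant,
                 init_scale = init_scale,
                 output_init_scale = output_init_scale,
                 seed = seed),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> %s, feedback '%s'\n",
              paste(x$layer_sizes, collapse = "-"), x$feedback_variant))
  print(x$params)
  invisible(x)
}

#' Save or load a network checkpoint
#'
#' Serialises the full network (sizes, weights, neuron parameters, feedback
#' matrices) to a portable JSON container, and restores it.
#'
#' @param net An `snn_network`.
#' @param path File path.
#' @return `read_checkpoint()` returns the restored `snn_network`;
#'   `write_checkpoint()` returns `path` invisibly.
#' @export
write_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  payload <- list(
    layer_sizes = net$layer_sizes,
    params = unclass(net$params),
    init_scale = net$init_scale,
    output_init_scale = net$output_init_scale,
    seed = net$seed,
    feedback_variant = net$feedback_variant,
    weights = lapply(net$weights, function(w) list(dim = dim(w),
                                                   data = as.vector(w))),
    feedback = lapply(net$feedback, function(fb) {
      list(dim = dim(fb$b), data = as.vector(fb$b), variant = fb$variant,
           value_set = fb$value_set, scale = fb$scale, seed = fb$seed)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- do.call(neuron_params, x$params)
  restore_mat <- function(m) {
    matrix(unlist(m$data), unlist(m$dim)[1], unlist(m$dim)[2])
  }
  weights <- lapply(x$weights, restore_mat)
  feedback <- lapply(x$feedback, function(fb) {
    b <- restore_mat(fb)
    out <- list(b = b, variant = fb$variant,
                value_set = unlist(fb$value_set),
                scale = fb$scale, seed = fb$seed)
    if (fb$variant == "pow2") {
      out$sign <- sign(b)
      out$m <- ifelse(b == 0, 0L, round(log2(abs(b))))
    }
    structure(out, class = "feedback_matrix")
  })
  structure(list(layer_sizes = as.integer(x$layer_sizes),
                 weights = weights,
                 feedback = feedback,
                 params = params,
                 feedback_variant = x$feedback_variant,
                 init_scale = x$init_scale,
                 output_init_scale = x$output_init_scale,
                 seed = x$seed),
            class = "snn_network")
}
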
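#' Fixed random direct-feedback matrix
#'
#' Creates the fixed random feedback matrix `B` that projects the output
#' layer's error vector directly onto one hidden layer (entry `B[i, l]`
#' connects output neuron `l` to hidden neuron `i`). The matrix is generated
#' once and never trained.
#'
#' Two variants are supported. `"real"` draws entries i.i.d. uniform on
#' `(-scale, scale)`; the default scale is RMS-matched to the default
#' power-of-2 value set so hidden-error magnitudes (and hence usable learning
#' rates) are comparable across variants. `"pow2"` draws entries i.i.d.
#' uniformly from a small set of signed powers of 2 (plus 0), the
#' hardware-friendly variant in which every feedback multiplication becomes a
#' sign-corrected arithmetic shift; the shift exponents `m` (`|b| = 2^m`),
#' signs and zero mask are precomputed and stored.
#'
#' @param n_hidden,n_out Dimensions: hidden-layer width and output-layer
#'   width.
#' @param variant `"pow2"` (default) or `"real"`.
#' @param value_set Allowed entries for the `"pow2"` variant; every nonzero
#'   element must be a signed power of 2. Default `{-4, -2, -1, 0, 1, 2, 4}`.
#' @param scale Half-width of the uniform distribution for the `"real"`
#'   variant; default `sqrt(3 * mean(value_set^2))` (RMS match).
#' @param seed Optional integer; when given, generation is reproducible and
#'   does not disturb the caller's RNG stream.
#' @return A `feedback_matrix`: list with `b` (n_hidden x n_out matrix),
#'   `variant`, `value_set`, `scale`, `seed`, and for the power-of-2 variant
#'   `m` (shift exponents), `sign` (-1/0/1) with `b == sign * 2^m`.
#' @examples
#' B <- make_feedback(30, 3, seed = 1)
#' unique(as.vector(B$b))
#' @export
make_feedback <- function(n_hidden, n_out,
                          variant = c("pow2", "real"),
                          value_set = c(-4, -2, -1, 0, 1, 2, 4),
                          scale = NULL, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(n_hidden >= 1, n_out >= 1)
  if (variant == "pow2") {
    if (!length(value_set)) stop("value_set must be nonempty", call. = FALSE)
    nz <- value_set[value_set != 0]
    if (length(nz) && any(abs(nz) != 2^round(log2(abs(nz))))) {
      stop("pow2 variant requires every nonzero value_set entry to be a ",
           "signed power of 2", call. = FALSE)
    }
  }
  if (is.null(scale)) scale <- sqrt(3 * mean(value_set^2))

  draw <- function() {
    if (variant == "pow2") {
      matrix(sample(value_set, n_hidden * n_out, replace = TRUE),
             n_hidden, n_out)
    } else {
      matrix(stats::runif(n_hidden * n_out, -scale, scale), n_hidden, n_out)
    }
  }
  b <- with_seed(seed, draw())

  out <- list(b = b, variant = variant, value_set = value_set,
              scale = scale, seed = seed)
  if (variant == "pow2") {
    out$sign <- sign(b)
    out$m <- ifelse(b == 0, 0L, round(log2(abs(b))))
  }
  structure(out, class = "feedback_matrix")
}

#' @export
print.feedback_matrix <- function(x, ...) {
  cat(sprintf("<feedback_matrix> %d x %d, variant '%s'\n",
              nrow(x$b), ncol(x$b), x$variant))
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
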
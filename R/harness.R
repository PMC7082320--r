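#' Train a network on a labelled spike-train dataset
#'
#' Runs per-example (online) training for up to `cfg$epochs` passes over the
#' dataset, in fixed order unless `cfg$shuffle` is set. Training accuracy of
#' an epoch is the fraction of examples whose forward pass (before that
#' example's update) predicted the correct class; prediction is the argmax
#' of output firing counts with ties resolved to the lowest neuron index.
#' Stops early once `cfg$stop_accuracy` (percent) is reached, if set.
#'
#' @param net [snn_network()].
#' @param data A dataset as produced by [make_rate_task()] (fields
#'   `examples`, `labels`).
#' @param cfg [train_config()].
#' @param rule Learning rule, see [train_example()].
#' @return List with the trained `net` and `log`, a data.frame with one row
#'   per epoch (`epoch`, `loss` = mean example loss, `accuracy` in percent).
#' @export
train_network <- function(net, data, cfg = train_config(),
                          rule = c("stdfa", "stdfa2", "bp", "frozen")) {
  rule <- match.arg(rule)
  n <- length(data$examples)
  stopifnot(n >= 1, length(data$labels) == n)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      loss_sum <- 0
      correct <- 0L
      for (idx in ord) {
        step <- train_example(net, data$examples[[idx]], data$labels[[idx]],
                              cfg, rule)
        net <- step$net
        loss_sum <- loss_sum + step$loss
        correct <- correct + as.integer(step$predicted == data$labels[[idx]])
      }
      acc <- 100 * correct / n
      log <- rbind(log, data.frame(epoch = epoch, loss = loss_sum / n,
                                   accuracy = acc))
      if (!is.null(cfg$stop_accuracy) && acc >= cfg$stop_accuracy) break
    }
  })
  list(net = net, log = log)
}

#' Classify spike-train examples with a trained network
#'
#' @param net [snn_network()].
#' @param examples List of binary input spike matrices.
#' @param quantize,formats Forward-pass mode, as in [forward_pass()].
#' @return Integer vector of predicted 1-based labels (argmax of output
#'   firing counts, ties to the lowest index).
#' @export
classify <- function(net, examples, quantize = FALSE,
                     formats = fp_defaults()) {
  vapply(examples, function(x) {
    fw <- forward_pass(net, x, quantize = quantize, formats = formats)
    which.max(fw$counts[[length(fw$counts)]])
  }, integer(1))
}

#' Run one training experiment
#'
#' End-to-end seed-deterministic run: generate the synthetic task, build the
#' network (feedback variant matched to the rule), train, and evaluate on a
#' freshly sampled test set drawn from the same class templates. All
#' randomness flows through seeds derived from `seed`, recorded in the
#' result; rerunning with the same configuration reproduces the result
#' bit for bit.
#'
#' @param rule `"stdfa"`, `"stdfa2"`, `"bp"`, or `"frozen"` (forward-only
#'   control).
#' @param task A [rate_task_spec()]; its `seed` field is overridden by
#'   `seed` so the whole run hangs off one number.
#' @param layer_sizes Network shape, e.g. `c(20, 30, 3)`; input and output
#'   widths must match the task.
#' @param cfg [train_config()].
#' @param seed Master seed of the run.
#' @param n_test Test examples per class.
#' @return An object of class `stdfa_experiment`: list with `rule`, `seed`,
#'   per-epoch `log`, `final_train_accuracy`, `best_train_accuracy`,
#'   `test_accuracy` (all percent), `epochs_run`, the trained `net`, and
#'   `config` (snapshot sufficient to reproduce the run).
#' @examples
#' \donttest{
#' r <- run_experiment("stdfa", rate_task_spec(n_per_class = 5),
#'                     cfg = train_config(epochs = 5), seed = 1)
#' r$log
#' }
#' @export
run_experiment <- function(rule = c("stdfa", "stdfa2", "bp", "frozen"),
                           task = rate_task_spec(),
                           layer_sizes = c(task$n_inputs, 30, task$n_classes),
                           cfg = train_config(), seed = 1, n_test = 10) {
  rule <- match.arg(rule)
  stopifnot(inherits(task, "rate_task_spec"))
  if (layer_sizes[1] != task$n_inputs ||
      layer_sizes[length(layer_sizes)] != task$n_classes) {
    stop("layer_sizes must start at the task's input width and end at its ",
         "class count", call. = FALSE)
  }
  # independent sub-streams for data, weights and training, all from `seed`
  task$seed <- seed * 1000L + 1L
  test_task <- task
  test_task$seed <- seed * 1000L + 2L
  test_task$n_per_class <- as.integer(n_test)
  net_seed <- seed * 1000L + 3L
  cfg$seed <- seed * 1000L + 4L

  data <- make_rate_task(task)
  test <- make_rate_task(test_task)
  variant <- if (rule == "stdfa2") "pow2" else "real"
  net <- snn_network(layer_sizes, feedback_variant = variant, seed = net_seed)

  fit <- train_network(net, data, cfg, rule)
  pred <- classify(fit$net, test$examples, quantize = cfg$quantize,
                   formats = cfg$formats)
  structure(list(
    rule = rule, seed = seed, log = fit$log,
    final_train_accuracy = utils::tail(fit$log$accuracy, 1L),
    best_train_accuracy = max(fit$log$accuracy),
    test_accuracy = 100 * mean(pred == test$labels),
    epochs_run = nrow(fit$log),
    net = fit$net,
    config = list(task = unclass(task), layer_sizes = layer_sizes,
                  cfg = unclass(cfg), seed = seed, n_test = n_test)
  ), class = "stdfa_experiment")
}

#' @export
print.stdfa_experiment <- function(x, ...) {
  cat(sprintf(paste0("<stdfa_experiment> rule '%s', seed %d: %d epoch(s), ",
                     "train %.1f%% (best %.1f%%), test %.1f%%\n"),
              x$rule, x$seed, x$epochs_run, x$final_train_accuracy,
              x$best_train_accuracy, x$test_accuracy))
  invisible(x)
}

#' @export
as.data.frame.stdfa_experiment <- function(x, ...) {
  data.frame(rule = x$rule, seed = x$seed, epochs_run = x$epochs_run,
             final_train_accuracy = x$final_train_accuracy,
             best_train_accuracy = x$best_train_accuracy,
             test_accuracy = x$test_accuracy)
}

#' Compare learning rules on shared data and seed
#'
#' Runs one experiment per rule with identical task, network shape and seed
#' (so all rules see the very same dataset) and tabulates the results.
#'
#' @inheritParams run_experiment
#' @param rules Character vector of rule names.
#' @return List with `table` (one data.frame row per rule) and `results`
#'   (the full `stdfa_experiment` objects, named by rule).
#' @export
compare_rules <- function(rules, task = rate_task_spec(),
                          layer_sizes = c(task$n_inputs, 30, task$n_classes),
                          cfg = train_config(), seed = 1, n_test = 10) {
  stopifnot(length(rules) >= 1)
  results <- lapply(rules, function(r) {
    run_experiment(r, task, layer_sizes, cfg, seed, n_test)
  })
  names(results) <- rules
  list(table = do.call(rbind, lapply(results, as.data.frame)),
       results = results)
}

#' Plot a training log
#'
#' Per-epoch loss and training accuracy of an experiment, as a two-panel
#' ggplot. Requires the ggplot2 package.
#'
#' @param object An `stdfa_experiment`.
#' @return A ggplot object.
#' @export
plot_training <- function(object) {
  stopifnot(inherits(object, "stdfa_experiment"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  log <- object$log
  long <- rbind(
    data.frame(epoch = log$epoch, metric = "mean loss", value = log$loss),
    data.frame(epoch = log$epoch, metric = "train accuracy (%)",
               value = log$accuracy)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = sprintf("Training run: %s (seed %d)",
                                  object$rule, object$seed),
                  x = "epoch", y = NULL)
}
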
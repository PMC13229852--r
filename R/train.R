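# Training orchestration: epochs, batches, evaluation, multi-seed runs.

#' Classification accuracy of a network on a dataset
#'
#' @param net a [network_params()] object.
#' @param dataset a `spike_dataset`.
#' @param sim a [sim_params()] object.
#' @return top-1 accuracy in [0, 1].
#' @export
evaluate_accuracy <- function(net, dataset, sim) {
  preds <- vapply(seq_along(dataset$rasters), function(s)
    forward_pass(dataset$rasters[[s]], net, sim)$pred, integer(1L))
  mean(preds == dataset$labels)
}

#' Train a network on a dataset with the online three-factor rules
#'
#' Mini-batch gradient descent: gradients are accumulated online over
#' `batch_size` sequences and applied as their batch mean. Eligibility
#' traces reset between sequences; delays are clamped after every update.
#'
#' @param net a [network_params()] object.
#' @param train_set,test_set `spike_dataset`s (`test_set` optional).
#' @param sim a [sim_params()] object.
#' @param rates a [learn_rates()] object.
#' @param learn a [learn_flags()] list.
#' @param epochs training epochs.
#' @param seed seed for the per-epoch shuffling.
#' @param verbose print one line per epoch.
#' @return list with the trained `net` and a data.frame `log` holding
#'   per-epoch `train_loss`, `train_acc` and (if a test set was given)
#'   `test_acc`.
#' @export
train_network <- function(net, train_set, sim = sim_params(),
                          rates = learn_rates(), learn = learn_flags(),
                          epochs = 10L, test_set = NULL, seed = 1L,
                          verbose = FALSE) {
  set.seed(seed)
  n <- length(train_set$rasters)
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    elig <- eligibility_state(net)
    loss_sum <- 0; correct <- 0
    for (s in seq_along(ord)) {
      idx <- ord[s]
      res <- train_sequence(train_set$rasters[[idx]],
                            train_set$labels[idx], net, sim, elig, learn)
      elig <- res$elig
      loss_sum <- loss_sum + res$loss
      correct <- correct + (res$pred == train_set$labels[idx])
      if (elig$n_seq >= rates$batch_size || s == length(ord)) {
        upd <- apply_updates(net, elig, rates, sim, learn)
        net <- upd$net; elig <- upd$elig
      }
    }
    row <- data.frame(epoch = ep, train_loss = loss_sum / n,
                      train_acc = correct / n)
    if (!is.null(test_set))
      row$test_acc <- evaluate_accuracy(net, test_set, sim)
    log_rows[[ep]] <- row
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  train %.3f%s\n", ep,
                  row$train_loss, row$train_acc,
                  if (is.null(test_set)) ""
                  else sprintf("  test %.3f", row$test_acc)))
  }
  list(net = net, log = do.call(rbind, log_rows))
}

#' Append a per-epoch training log as JSON lines
#'
#' @param log data.frame as produced by [train_network()].
#' @param path output file; one JSON object per epoch row.
#' @export
write_train_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything that defines one experiment. Serializable to/from
#' YAML with [write_run_config()] / [read_run_config()].
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param recurrent recurrent hidden layer.
#' @param flavor_in,flavor_rec delay flavor per projection.
#' @param learn_weights,learn_delays learnable-group switches (weights
#'   covers input/recurrent/readout weights; delays covers both delay
#'   projections).
#' @param delay_init delay initialization mode (see [init_network()]);
#'   `"integer"` is the fixed-random-delay control condition.
#' @param density_in,density_rec sparsity mask densities.
#' @param sim a [sim_params()] object.
#' @param rates a [learn_rates()] object.
#' @param epochs training epochs.
#' @param seeds integer vector: one full run per seed.
#' @param task a [latency_task_spec()] describing the synthetic dataset.
#' @param n_train,n_test dataset sizes (fresh seeded test set; no
#'   validation set is used).
#' @param shd_train,shd_test optional paths to SHD/SSC HDF5 files; when
#'   set they replace the synthetic datasets (see [load_shd()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_in = 4L, n_hidden = 8L, n_out = 2L,
                       recurrent = FALSE,
                       flavor_in = "synaptic", flavor_rec = "none",
                       learn_weights = TRUE, learn_delays = TRUE,
                       delay_init = "uniform",
                       density_in = 1, density_rec = 1,
                       sim = sim_params(), rates = learn_rates(),
                       epochs = 10L, seeds = 1:5,
                       task = latency_task_spec(),
                       n_train = 64L, n_test = 32L,
                       shd_train = NULL, shd_test = NULL) {
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 recurrent = recurrent, flavor_in = flavor_in,
                 flavor_rec = flavor_rec, learn_weights = learn_weights,
                 learn_delays = learn_delays, delay_init = delay_init,
                 density_in = density_in, density_rec = density_rec,
                 sim = sim, rates = rates, epochs = epochs, seeds = seeds,
                 task = task, n_train = n_train, n_test = n_test,
                 shd_train = shd_train, shd_test = shd_test),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # empty YAML nodes (written for absent optional fields) mean NULL
  y[vapply(y, function(e) length(e) == 0L, logical(1))] <- NULL
  y$sim <- do.call(sim_params, y$sim[setdiff(names(y$sim), character(0))])
  y$rates <- do.call(learn_rates, y$rates)
  tk <- y$task
  y$task <- latency_task_spec(
    n_in = tk$n_in, n_classes = tk$n_classes, T = tk$T, dt = tk$dt,
    max_offset = tk$max_offset, spikes_per_channel = tk$spikes_per_channel,
    jitter_sd = tk$jitter_sd,
    planted_latencies = matrix(unlist(tk$planted_latencies),
                               nrow = tk$n_classes),
    min_gap = tk$min_gap, tail_margin = tk$tail_margin, seed = tk$seed)
  do.call(run_config, y)
}

config_learn_flags <- function(config) {
  learn_flags(w_in = config$learn_weights, w_rec = config$learn_weights,
              w_out = config$learn_weights,
              d_in = config$learn_delays, d_rec = config$learn_delays)
}

config_network <- function(config, seed) {
  init_network(config$n_in, config$n_hidden, config$n_out,
               sim = config$sim, recurrent = config$recurrent,
               flavor_in = config$flavor_in, flavor_rec = config$flavor_rec,
               density_in = config$density_in,
               density_rec = config$density_rec,
               delay_init = config$delay_init, seed = seed)
}

config_datasets <- function(config, seed) {
  if (!is.null(config$shd_train)) {
    return(list(train = load_shd(config$shd_train),
                test = load_shd(config$shd_test)))
  }
  list(train = make_latency_dataset(config$task, config$n_train,
                                    seed = seed * 1000L + 1L),
       test = make_latency_dataset(config$task, config$n_test,
                                   seed = seed * 1000L + 2L))
}

#' Run one training experiment over its seed list
#'
#' Trains one network per seed (fresh seeded train and test sets each
#' time), evaluates top-1 test accuracy per epoch and reports the
#' across-seed mean with a t-distribution 95% confidence interval.
#'
#' @param config a [run_config()].
#' @param verbose print per-epoch progress.
#' @return list with `per_seed` (data.frame of final accuracies),
#'   `mean_acc`, `ci95` (half-width), and the per-seed training `logs`.
#' @export
run_training <- function(config, verbose = FALSE) {
  accs <- numeric(length(config$seeds))
  logs <- vector("list", length(config$seeds))
  for (k in seq_along(config$seeds)) {
    seed <- config$seeds[k]
    ds <- config_datasets(config, seed)
    net <- config_network(config, seed)
    fit <- train_network(net, ds$train, config$sim, config$rates,
                         config_learn_flags(config), config$epochs,
                         test_set = NULL, seed = seed, verbose = verbose)
    accs[k] <- evaluate_accuracy(fit$net, ds$test, config$sim)
    logs[[k]] <- fit$log
  }
  n <- length(accs)
  ci <- if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(accs) / sqrt(n)
        else NA_real_
  list(per_seed = data.frame(seed = config$seeds, test_acc = accs),
       mean_acc = mean(accs), ci95 = ci, logs = logs)
}

#' Delay-placement ablation for recurrent networks
#'
#' Re-runs [run_training()] with delays placed at the input projection,
#' the recurrent projection, or both, under fixed and learnable delay
#' conditions, sharing seeds across conditions.
#'
#' @param config a recurrent [run_config()].
#' @param placements subset of `c("input", "recurrent", "both")`.
#' @param conditions subset of `c("learnable", "fixed")`.
#' @return data.frame with one row per placement x condition.
#' @export
run_ablation <- function(config,
                         placements = c("input", "recurrent", "both"),
                         conditions = c("learnable", "fixed")) {
  if (!config$recurrent) stop("placement ablations require `recurrent = TRUE`")
  base_flavor <- if (config$flavor_in == "none") "synaptic" else config$flavor_in
  rows <- list()
  for (pl in placements) for (cond in conditions) {
    cfg <- config
    cfg$flavor_in <- if (pl %in% c("input", "both")) base_flavor else "none"
    cfg$flavor_rec <- if (pl %in% c("recurrent", "both")) base_flavor else "none"
    cfg$learn_delays <- cond == "learnable"
    if (cond == "fixed") cfg$delay_init <- "integer"
    res <- run_training(cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      placement = pl, condition = cond, mean_acc = res$mean_acc,
      ci95 = res$ci95,
      params = param_count(cfg$n_in, cfg$n_hidden, cfg$n_out,
                           flavor_in = cfg$flavor_in,
                           flavor_rec = cfg$flavor_rec,
                           recurrent = TRUE,
                           density_in = cfg$density_in,
                           density_rec = cfg$density_rec))
  }
  do.call(rbind, rows)
}
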
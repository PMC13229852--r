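# Packaged experiments probing delay learning on the synthetic tasks.

#' Relative delay offsets of a network's input projection
#'
#' Coincidence detection only constrains delays up to a common
#' per-neuron shift, so learned delays are compared on relative offsets:
#' for each hidden neuron, the continuous delay shift of every channel
#' minus that of channel 1.
#'
#' @param net a [network_params()] with synaptic input delays.
#' @param sim a [sim_params()] object.
#' @return `n_hidden x n_in` matrix of relative offsets (column 1 zero).
#' @export
relative_delay_offsets <- function(net, sim) {
  if (net$flavor_in != "synaptic")
    stop("relative offsets are defined for synaptic input delays")
  sh <- delay_shifts(net, sim, "in")
  sh - sh[, 1L]
}

#' Delay-recovery experiment on the planted-latency task
#'
#' Trains only the input delays of the hand-constructed coincidence
#' probe network ([latency_probe_network()], weights frozen, delays
#' initialized at the midpoint) on a planted-latency dataset, then
#' scores how close the learned relative delay offsets come to the
#' planted relative latencies of each neuron's class, and the resulting
#' test accuracy.
#'
#' The recovery run uses a two-channel, two-class task by default: the
#' per-neuron delay landscape is then one-dimensional, so the experiment
#' isolates the learning rule's convergence from the combinatorics of
#' partial multi-channel coincidences. The probe weights are set so the
#' detector fires when its two inputs arrive within one step of each
#' other and stays silent beyond that, and recovery is scored on the
#' rounded (integer) relative offsets actually used by the binary
#' forward pass.
#'
#' @param seed experiment seed (task latencies, datasets, shuffling).
#' @param task a [latency_task_spec()]; its `seed` is replaced by `seed`.
#' @param sim a [sim_params()] object.
#' @param rates a [learn_rates()] object (the delay learning rate is the
#'   operative one; weights are frozen).
#' @param w_sum summed probe input weight (see [latency_probe_network()]).
#' @param readout_scale multiplier on the probe's fixed readout weights.
#' @param epochs training epochs.
#' @param n_train,n_test dataset sizes.
#' @return list with `max_offset_error` (largest absolute deviation, in
#'   steps, between the learned and planted integer relative offsets over
#'   all neurons/channels), `test_acc`, the trained `net`, and the
#'   planted and learned offset matrices.
#' @export
delay_recovery_run <- function(seed = 1L,
                               task = latency_task_spec(
                                 n_in = 2L, n_classes = 2L, T = 64L,
                                 max_offset = 5L, min_gap = 12L,
                                 jitter_sd = 0),
                               sim = sim_params(),
                               rates = learn_rates(),
                               w_sum = 1.36, readout_scale = 2.5,
                               epochs = 40L, n_train = 128L, n_test = 48L) {
  task <- latency_task_spec(
    n_in = task$n_in, n_classes = task$n_classes, T = task$T, dt = task$dt,
    max_offset = task$max_offset,
    spikes_per_channel = task$spikes_per_channel,
    jitter_sd = task$jitter_sd, min_gap = task$min_gap,
    tail_margin = task$tail_margin, seed = seed)
  train <- make_latency_dataset(task, n_train, seed = seed * 1000L + 1L)
  test <- make_latency_dataset(task, n_test, seed = seed * 1000L + 2L)
  net <- latency_probe_network(task, sim, planted = FALSE, w_sum = w_sum)
  net$W_out <- net$W_out * readout_scale
  learn <- learn_flags(w_in = FALSE, w_rec = FALSE, w_out = FALSE,
                       d_in = TRUE, d_rec = FALSE)
  fit <- train_network(net, train, sim, rates, learn, epochs = epochs,
                       seed = seed)
  learned <- relative_delay_offsets(fit$net, sim)
  deff <- effective_delay(fit$net$D_in, sim$D_max)
  learned_int <- deff - deff[, 1L]
  planted <- task$planted_latencies -
    task$planted_latencies[, 1L]          # relative planted offsets
  list(max_offset_error = max(abs(learned_int - planted)),
       test_acc = evaluate_accuracy(fit$net, test, sim),
       net = fit$net, planted = planted, learned = learned,
       learned_int = learned_int, log = fit$log)
}

#' Learnable vs fixed delays on the planted-latency task
#'
#' The scaled-down directional control: a 16-hidden-unit network
#' co-learning weights and delays versus the same network with fixed
#' random integer delays, same seed, same data; final test accuracies
#' are compared. Input weights are drawn positive and scaled so the
#' hidden layer operates in the coincidence-detection regime from the
#' start (row sums around 1.5--2 thresholds); at the reference learning
#' rates a plain 1/sqrt(fan-in) initialization barely leaves chance
#' level within a desk-scale budget, which would make the comparison
#' vacuous.
#'
#' @param seed shared seed for both conditions (task latencies,
#'   datasets, initialization, shuffling).
#' @param task a [latency_task_spec()]; its `seed` is replaced by
#'   `seed`.
#' @param sim a [sim_params()] object.
#' @param rates a [learn_rates()] object.
#' @param n_hidden hidden layer size.
#' @param w_in_scale multiplier on the positive input weights.
#' @param epochs,n_train,n_test experiment scale.
#' @return data.frame with one row per condition.
#' @export
learnable_vs_fixed_run <- function(seed,
                                   task = latency_task_spec(
                                     n_in = 6L, n_classes = 2L, T = 64L,
                                     max_offset = 6L, min_gap = 12L,
                                     jitter_sd = 0.5),
                                   sim = sim_params(),
                                   rates = learn_rates(),
                                   n_hidden = 16L, w_in_scale = 1.5,
                                   epochs = 25L, n_train = 128L,
                                   n_test = 48L) {
  task <- latency_task_spec(
    n_in = task$n_in, n_classes = task$n_classes, T = task$T, dt = task$dt,
    max_offset = task$max_offset,
    spikes_per_channel = task$spikes_per_channel,
    jitter_sd = task$jitter_sd, min_gap = task$min_gap,
    tail_margin = task$tail_margin, seed = seed)
  train <- make_latency_dataset(task, n_train, seed = seed * 1000L + 1L)
  test <- make_latency_dataset(task, n_test, seed = seed * 1000L + 2L)
  rows <- lapply(c("learnable", "fixed"), function(cond) {
    net <- init_network(task$n_in, n_hidden, task$n_classes, sim,
                        flavor_in = "synaptic",
                        delay_init = if (cond == "fixed") "integer"
                                     else "uniform",
                        seed = seed)
    net$W_in <- abs(net$W_in) * w_in_scale
    fl <- learn_flags(w_rec = FALSE, d_rec = FALSE,
                      d_in = cond == "learnable")
    fit <- train_network(net, train, sim, rates, fl, epochs = epochs,
                         seed = seed)
    data.frame(seed = seed, condition = cond,
               test_acc = evaluate_accuracy(fit$net, test, sim))
  })
  do.call(rbind, rows)
}
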
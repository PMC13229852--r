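# Training orchestration, configs and reporting.

small_config <- function(...) {
  run_config(n_in = 2L, n_hidden = 2L, n_out = 2L,
             task = latency_task_spec(n_in = 2L, T = 48L, max_offset = 5L,
                                      spikes_per_channel = 3L,
                                      min_gap = 10L, seed = 1),
             rates = learn_rates(batch_size = 8L),
             epochs = 2L, seeds = 1:2, n_train = 16L, n_test = 8L, ...)
}

test_that("run_training is deterministic and reports a t-based CI", {
  cfg <- small_config()
  r1 <- run_training(cfg)
  r2 <- run_training(cfg)
  expect_identical(r1$per_seed, r2$per_seed)
  expect_equal(r1$mean_acc, mean(r1$per_seed$test_acc))
  expect_equal(r1$ci95,
               stats::qt(0.975, 1) * stats::sd(r1$per_seed$test_acc) / sqrt(2))
  expect_equal(nrow(r1$logs[[1]]), cfg$epochs)
})

test_that("five seeds use the t(4) quantile 2.776 on the seed standard error", {
  expect_equal(stats::qt(0.975, 4), 2.776445, tolerance = 1e-6)
  cfg <- small_config()
  cfg$seeds <- 1:5
  cfg$epochs <- 1L
  r <- run_training(cfg)
  expect_equal(r$ci95,
               2.776445 * stats::sd(r$per_seed$test_acc) / sqrt(5),
               tolerance = 1e-6)
})

test_that("turning delay learning off equals a fixed-delay run bit for bit", {
  cfg <- small_config(learn_delays = FALSE)
  ds <- delayprop:::config_datasets(cfg, 1L)
  net <- delayprop:::config_network(cfg, 1L)
  f1 <- train_network(net, ds$train, cfg$sim, cfg$rates,
                      delayprop:::config_learn_flags(cfg), cfg$epochs,
                      seed = 1L)
  f2 <- train_network(net, ds$train, cfg$sim, cfg$rates,
                      learn_flags(d_in = FALSE, d_rec = FALSE), cfg$epochs,
                      seed = 1L)
  expect_identical(f1$net$W_in, f2$net$W_in)
  expect_identical(f1$net$D_in, f2$net$D_in)
})

test_that("ablation sweeps placements with matching parameter accounting", {
  cfg <- small_config()
  cfg$recurrent <- TRUE
  cfg$flavor_rec <- "synaptic"
  cfg$epochs <- 1L
  cfg$seeds <- 1L
  ab <- run_ablation(cfg, placements = c("input", "recurrent", "both"),
                     conditions = "learnable")
  expect_equal(nrow(ab), 3L)
  none <- param_count(cfg$n_in, cfg$n_hidden, cfg$n_out, recurrent = TRUE)
  extra <- ab$params - none
  expect_equal(extra[3], extra[1] + extra[2])  # "both" adds input + recurrent
  expect_error(run_ablation(small_config()), "recurrent")
})

test_that("run configs round-trip through YAML", {
  cfg <- small_config()
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$n_hidden, cfg$n_hidden)
  expect_equal(cfg2$sim$alpha, cfg$sim$alpha)
  expect_equal(cfg2$rates$lr_d, cfg$rates$lr_d)
  expect_equal(cfg2$task$planted_latencies, cfg$task$planted_latencies)
  r1 <- run_training(cfg); r2 <- run_training(cfg2)
  expect_identical(r1$per_seed, r2$per_seed)
})

test_that("training logs export as JSON lines", {
  log <- data.frame(epoch = 1:2, train_loss = c(1.5, 1.2),
                    train_acc = c(0.5, 0.75))
  f <- tempfile(fileext = ".jsonl")
  write_train_log(log, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$train_acc, 0.75)
})

test_that("training reduces the loss on the coincidence discrimination task", {
  # two-channel task: one class coincident, one offset by 3 steps
  sim <- sim_params()
  task <- latency_task_spec(n_in = 2L, n_classes = 2L, T = 56L,
                            max_offset = 3L, min_gap = 10L,
                            planted_latencies = rbind(c(0L, 0L), c(0L, 3L)))
  train <- make_latency_dataset(task, 48, seed = 31)
  for (delays_on in c(TRUE, FALSE)) {
    net <- latency_probe_network(task, sim, planted = FALSE, w_sum = 1.2)
    net$W_out <- net$W_out * 2.5
    fl <- learn_flags(w_rec = FALSE, d_rec = FALSE, d_in = delays_on)
    fit <- train_network(net, train, sim, learn_rates(), fl,
                         epochs = 5L, seed = 3L)
    # averaged training loss decreases over the first epochs
    expect_lt(mean(fit$log$train_loss[4:5]), mean(fit$log$train_loss[1:2]))
  }
})
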
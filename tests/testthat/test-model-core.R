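# Discrete-time LIF dynamics, delays, readout and loss.

test_that("effective_delay maps the continuous range onto [0, D_max-1]", {
  expect_identical(effective_delay(-12, 25), 0L)
  expect_identical(effective_delay(12, 25), 24L)
  expect_identical(effective_delay(0, 25), 12L)
  # clipping absorbs out-of-range values
  expect_identical(effective_delay(-99, 25), 0L)
  expect_identical(effective_delay(99, 25), 24L)
  # round half up, elementwise
  expect_identical(effective_delay(c(-11.5, -11.4), 25), c(1L, 1L))
})

test_that("lif_step implements leak, weighted delayed input and soft reset", {
  sim <- sim_params(alpha = 0.6, v_th = 1)
  net <- network_params(W_in = matrix(0.2, 1, 1), W_out = matrix(0, 1, 1),
                        D_in = matrix(-12, 1, 1), flavor_in = "synaptic")
  st <- neuron_state(net, sim)
  st$v <- 0.5
  st <- lif_step(st, 1, net, sim)   # weighted input 0.2, no reset
  expect_equal(st$v, 0.6 * 0.5 + 0.2)
  expect_equal(st$z, 0)

  st2 <- neuron_state(net, sim)
  st2$v <- 1.5; st2$z <- 1
  st2 <- lif_step(st2, 0, net, sim) # reset by threshold subtraction
  expect_equal(st2$v, 0.6 * 1.5 - 1)
  expect_equal(st2$z, 0)

  # zero input, zero state is a fixed point
  st3 <- neuron_state(net, sim)
  for (i in 1:5) st3 <- lif_step(st3, 0, net, sim)
  expect_equal(st3$v, 0)
})

test_that("spiking uses strict inequality v > v_th", {
  sim <- sim_params(v_th = 1)
  net <- network_params(W_in = matrix(1, 1, 1), W_out = matrix(0, 1, 1),
                        D_in = matrix(-12, 1, 1), flavor_in = "synaptic")
  st <- lif_step(neuron_state(net, sim), 1, net, sim)  # v exactly at v_th
  expect_equal(st$z, 0)
})

test_that("delayed inputs arrive effective_delay steps later", {
  sim <- sim_params()
  for (d_eff in c(0L, 3L, 7L)) {
    net <- network_params(W_in = matrix(2, 1, 1), W_out = matrix(0, 1, 1),
                          D_in = matrix(d_eff - 12, 1, 1),
                          flavor_in = "synaptic")
    x <- matrix(0, 15, 1); x[2, 1] <- 1
    fp <- forward_pass(x, net, sim)
    expect_equal(which(fp$z == 1), 2L + d_eff)
  }
})

test_that("srnn_step reduces to lif_step for W_rec = 0 and errors without W_rec", {
  sim <- sim_params()
  set.seed(3)
  x <- random_raster(20, 3)
  net_ff <- random_ff_net(3, 4, 2, sim, seed = 5)
  net_rec <- network_params(net_ff$W_in, net_ff$W_out,
                            W_rec = matrix(0, 4, 4),
                            D_in = net_ff$D_in, D_rec = matrix(0, 4, 4),
                            flavor_in = "synaptic", flavor_rec = "synaptic")
  fp1 <- forward_pass(x, net_ff, sim)
  fp2 <- forward_pass(x, net_rec, sim)
  expect_equal(fp1$z, fp2$z)
  expect_equal(fp1$y, fp2$y)
  expect_error(srnn_step(neuron_state(net_ff, sim), c(0, 0, 0), net_ff, sim),
               "W_rec")
})

test_that("recurrence carries one mandatory step of latency plus the delay", {
  sim <- sim_params()
  # neuron 1 driven to spike at t=2; neuron 2 fed only recurrently
  for (d_rec in c(0L, 4L)) {
    W_rec <- matrix(0, 2, 2); W_rec[2, 1] <- 2
    D_rec <- matrix(-12, 2, 2); D_rec[2, 1] <- d_rec - 12
    net <- network_params(W_in = matrix(c(2, 0), 2, 1),
                          W_out = matrix(0, 1, 2), W_rec = W_rec,
                          D_in = matrix(-12, 2, 1), D_rec = D_rec,
                          flavor_in = "synaptic", flavor_rec = "synaptic")
    x <- matrix(0, 15, 1); x[2, 1] <- 1
    fp <- forward_pass(x, net, sim)
    expect_equal(which(fp$z[, 1] == 1), 2L)
    expect_equal(which(fp$z[, 2] == 1), 3L + d_rec)  # t+1+delay
  }
})

test_that("a two-neuron loop sustains alternating firing with delay-dependent period", {
  sim <- sim_params()
  W_rec <- matrix(0, 2, 2); W_rec[2, 1] <- 1.5; W_rec[1, 2] <- 1.5
  x <- matrix(0, 40, 1); x[2, 1] <- 1
  period <- function(d_eff) {
    D_rec <- matrix(d_eff - 12, 2, 2)
    net <- network_params(W_in = matrix(c(2, 0), 2, 1),
                          W_out = matrix(0, 1, 2), W_rec = W_rec,
                          D_in = matrix(-12, 2, 1), D_rec = D_rec,
                          flavor_in = "synaptic", flavor_rec = "synaptic")
    fp <- forward_pass(x, net, sim)
    t1 <- which(fp$z[, 1] == 1)
    expect_gt(length(t1), 2)       # self-sustained
    unique(diff(t1))
  }
  p0 <- period(0L)
  p3 <- period(3L)
  expect_length(p0, 1L)            # regular firing
  expect_length(p3, 1L)
  expect_equal(p3 - p0, 2L * 3L)   # each loop traversal adds the delay twice
})

test_that("readout is a leaky integrator: geometric decay and closed form", {
  sim <- sim_params(kappa = 0.99)
  net <- network_params(W_in = matrix(1.5, 1, 1), W_out = matrix(1, 1, 1),
                        D_in = matrix(-12, 1, 1), flavor_in = "synaptic")
  x <- matrix(0, 30, 1); x[1, 1] <- 1   # single hidden spike at t = 1
  fp <- forward_pass(x, net, sim)
  expect_equal(fp$z[1, 1], 1)
  expect_equal(sum(fp$z), 1)
  expect_equal(fp$y[, 1], 0.99^(0:29), tolerance = 1e-12)
})

test_that("forward_pass matches the step-function reference implementation", {
  sim <- sim_params()
  set.seed(11)
  x <- random_raster(25, 4)
  net <- init_network(4, 3, 2, sim, recurrent = TRUE,
                      flavor_in = "synaptic", flavor_rec = "axonal",
                      seed = 9)
  net$W_in <- net$W_in * 6; net$W_rec <- net$W_rec * 3
  fp <- forward_pass(x, net, sim)
  st <- neuron_state(net, sim)
  for (t in seq_len(nrow(x))) {
    st <- srnn_step(st, x[t, ], net, sim)
    st <- readout_step(st, net, sim)
    expect_equal(st$v, fp$v[t, ])
    expect_equal(st$z, fp$z[t, ])
    expect_equal(st$y, fp$y[t, ])
  }
})

test_that("simulation is Markov: chunked simulation equals one pass", {
  sim <- sim_params()
  set.seed(21)
  x <- random_raster(30, 3)
  net <- init_network(3, 4, 2, sim, recurrent = TRUE,
                      flavor_in = "axonal", flavor_rec = "synaptic",
                      seed = 2)
  net$W_in <- net$W_in * 6; net$W_rec <- net$W_rec * 2
  full <- forward_pass(x, net, sim)
  a <- forward_pass(x[1:13, , drop = FALSE], net, sim)
  b <- forward_pass(x[14:30, , drop = FALSE], net, sim, state = a$state)
  expect_equal(rbind(a$z, b$z), full$z)
  expect_equal(rbind(a$y, b$y), full$y, tolerance = 1e-12)
})

test_that("membrane equals the causal geometric convolution when never spiking", {
  sim <- sim_params(v_th = 1e9)
  set.seed(4)
  x <- random_raster(40, 3)
  net <- random_ff_net(3, 2, 2, sim, flavor = "axonal", seed = 7)
  fp <- forward_pass(x, net, sim)
  de <- effective_delay(net$D_in, sim$D_max)
  xd <- vapply(1:3, function(i)
    c(numeric(de[i]), x[, i])[1:40], numeric(40))
  Iall <- xd %*% t(net$W_in)
  vT <- colSums(sim$alpha^((39:0)) * Iall)
  expect_equal(fp$v[40, ], vT, tolerance = 1e-10)
})

test_that("masked synapses never contribute to the membrane", {
  sim <- sim_params()
  set.seed(5)
  x <- random_raster(25, 6)
  mask <- make_sparsity_mask(c(4, 6), 0.5, seed = 8)
  net <- init_network(6, 4, 2, sim, flavor_in = "synaptic",
                      seed = 3)
  net$W_in <- net$W_in * 6
  net_m <- network_params(net$W_in, net$W_out, D_in = net$D_in,
                          flavor_in = "synaptic", mask_in = mask)
  # zeroing the masked weights by hand gives the identical trajectory
  net_z <- network_params(net$W_in * mask, net$W_out, D_in = net$D_in,
                          flavor_in = "synaptic")
  expect_equal(forward_pass(x, net_m, sim)$v, forward_pass(x, net_z, sim)$v)
  expect_true(all(net_m$W_in[mask == 0] == 0))
})

test_that("softmax outputs normalize and the uniform case gives E = T log K", {
  sim <- sim_params()
  set.seed(6)
  x <- random_raster(20, 3)
  net <- random_ff_net(3, 4, 20, sim, seed = 12)
  fp <- forward_pass(x, net, sim, label = 1L)
  expect_true(all(abs(rowSums(fp$pi_hat) - 1) < 1e-12))
  # zero readout weights: uniform softmax at every step
  net$W_out <- net$W_out * 0
  fp0 <- forward_pass(x[1, , drop = FALSE], net, sim, label = 3L)
  expect_equal(fp0$E, log(20), tolerance = 1e-12)
})

test_that("cross-entropy loss matches hand arithmetic on a crafted readout", {
  sim <- sim_params(kappa = 0.5)
  # one hidden neuron spiking at t = 1 and t = 2, readout weights (1, -1)
  net <- network_params(W_in = matrix(5, 1, 1),
                        W_out = matrix(c(1, -1), 2, 1),
                        D_in = matrix(-12, 1, 1), flavor_in = "synaptic")
  x <- matrix(c(1, 1), 2, 1)
  fp <- forward_pass(x, net, sim, label = 1L)
  y1 <- c(1, -1); y2 <- 0.5 * y1 + c(1, -1)
  E_hand <- -log(exp(y1[1]) / sum(exp(y1))) - log(exp(y2[1]) / sum(exp(y2)))
  expect_equal(fp$E, E_hand, tolerance = 1e-12)
  expect_equal(fp$pred, 1L)
})

test_that("sharpening the readout lowers the loss when the argmax is correct", {
  sim <- sim_params()
  set.seed(31)
  x <- random_raster(20, 3)
  net <- random_ff_net(3, 4, 3, sim, seed = 14)
  fp <- forward_pass(x, net, sim)
  lab <- fp$pred
  E1 <- forward_pass(x, net, sim, label = lab)$E
  net2 <- net; net2$W_out <- net$W_out * 2
  E2 <- forward_pass(x, net2, sim, label = lab)$E
  expect_lt(E2, E1)
})

test_that("raster and checkpoint round-trips preserve content", {
  r <- spike_raster(matrix(rbinom(60, 1, 0.3), 20, 3), dt = 10, label = 2L)
  f <- tempfile(fileext = ".tsv.gz")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_equal(r2$spikes, r$spikes)
  expect_equal(r2$dt, r$dt)
  expect_equal(r2$label, r$label)
  sim <- sim_params()
  net <- init_network(3, 2, 2, sim, seed = 1)
  f2 <- tempfile(fileext = ".rds")
  write_checkpoint(net, sim, f2)
  ck <- read_checkpoint(f2)
  expect_equal(ck$net$W_in, net$W_in)
  expect_equal(ck$sim$alpha, sim$alpha)
})
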
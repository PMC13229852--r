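# Online three-factor learning rules.

test_that("learning signal: hand value, zero at perfect prediction, filtering", {
  W_out <- matrix(c(1, -1), 2, 1)   # one hidden neuron, two classes
  pi_hat <- matrix(c(0.8, 0.2), 1, 2)
  L <- learning_signal(pi_hat, label = 1L, W_out, kappa = 0.99, "online")
  expect_equal(L[1, 1], 1 * (0.8 - 1) + (-1) * 0.2)   # -0.4
  # perfect prediction at every step gives a zero signal
  Lp <- learning_signal(matrix(c(1, 0), 1, 2), 1L, W_out, 0.99, "online")
  expect_equal(Lp[1, 1], 0)
  # offline mode applies the kappa^{t'-t} future filter
  ph <- matrix(c(0.6, 0.7, 0.4, 0.3), 2, 2)
  kap <- 0.5
  Lon <- learning_signal(ph, 1L, W_out, kap, "online")
  Loff <- learning_signal(ph, 1L, W_out, kap, "offline")
  expect_equal(Loff[2, ], Lon[2, ])
  expect_equal(Loff[1, ], Lon[1, ] + kap * Lon[2, ])
})

test_that("a zero learning signal leaves hidden-parameter gradients at zero", {
  sim <- sim_params()
  set.seed(10)
  x <- random_raster(20, 4)
  net <- random_ff_net(4, 3, 2, sim, seed = 2)
  net$W_out <- net$W_out * 0
  res <- train_sequence(x, 1L, net, sim, eligibility_state(net))
  expect_equal(max(abs(res$elig$gW_in)), 0)
  expect_equal(max(abs(res$elig$gD_in)), 0)
  # the readout itself still learns
  expect_gt(max(abs(res$elig$gW_out)), 0)
})

test_that("delay eligibility is linear in the synaptic weight", {
  # the kernel-derivative drive is W * dx_hat/dD, so at a fixed membrane
  # trajectory the delay gradient is proportional to W; probe with a
  # negligibly weighted channel that cannot perturb the dynamics
  sim <- sim_params()
  set.seed(12)
  x <- random_raster(25, 2)
  gD_for <- function(w_b) {
    net <- network_params(W_in = matrix(c(1.5, w_b), 1, 2),
                          W_out = matrix(c(1, -1), 2, 1),
                          D_in = matrix(c(0, 2), 1, 2),
                          flavor_in = "synaptic")
    train_sequence(x, 1L, net, sim, eligibility_state(net))$elig$gD_in
  }
  gp <- gD_for(1e-6); gm <- gD_for(-1e-6); g0 <- gD_for(0)
  expect_equal(gp[1, 2], -gm[1, 2], tolerance = 1e-4)
  expect_equal(gD_for(2e-6)[1, 2], 2 * gp[1, 2], tolerance = 1e-4)
  expect_equal(g0[1, 2], 0)   # a zero weight gives exactly zero eligibility
})

test_that("gradients accumulate additively over sequences", {
  sim <- sim_params()
  set.seed(14)
  x <- random_raster(20, 4)
  net <- random_ff_net(4, 3, 2, sim, seed = 3)
  e1 <- train_sequence(x, 2L, net, sim, eligibility_state(net))$elig
  e2 <- train_sequence(x, 2L, net, sim, e1)$elig
  expect_equal(e2$gW_in, 2 * e1$gW_in, tolerance = 1e-12)
  expect_equal(e2$gD_in, 2 * e1$gD_in, tolerance = 1e-12)
  expect_equal(e2$n_seq, 2L)
})

test_that("an axonal delay shared by identical synapses sums the synaptic gradients", {
  sim <- sim_params()
  set.seed(15)
  x <- random_raster(30, 3)
  W_in <- matrix(runif(12, -1, 1) * 2, 4, 3)
  W_out <- matrix(runif(8, -1, 1), 2, 4)
  d <- runif(3, -5, 5)
  net_ax <- network_params(W_in, W_out, D_in = d, flavor_in = "axonal")
  net_sy <- network_params(W_in, W_out,
                           D_in = matrix(d, 4, 3, byrow = TRUE),
                           flavor_in = "synaptic")
  g_ax <- train_sequence(x, 1L, net_ax, sim,
                         eligibility_state(net_ax))$elig$gD_in
  g_sy <- train_sequence(x, 1L, net_sy, sim,
                         eligibility_state(net_sy))$elig$gD_in
  expect_equal(g_ax, colSums(g_sy), tolerance = 1e-10)
})

test_that("disabling delay learning leaves dynamics and weight grads unchanged", {
  sim <- sim_params()
  set.seed(16)
  x <- random_raster(25, 4)
  net <- random_ff_net(4, 3, 2, sim, seed = 8)
  on <- train_sequence(x, 1L, net, sim, eligibility_state(net),
                       learn_flags())
  off <- train_sequence(x, 1L, net, sim, eligibility_state(net),
                        learn_flags(d_in = FALSE, d_rec = FALSE))
  expect_equal(on$loss, off$loss)
  expect_equal(on$pred, off$pred)
  expect_equal(on$elig$gW_in, off$elig$gW_in)
  expect_equal(max(abs(off$elig$gD_in)), 0)
})

test_that("online and offline-exact learning-signal modes agree", {
  sim <- sim_params()
  set.seed(17)
  for (rep in 1:3) {
    flavor <- c("synaptic", "axonal", "none")[rep]
    net <- random_ff_net(5, 4, 3, sim, flavor = flavor, seed = rep + 20)
    x <- random_raster(40, 5)
    e1 <- train_sequence(x, 2L, net, sim, eligibility_state(net),
                         signal_mode = "online")$elig
    e2 <- train_sequence(x, 2L, net, sim, eligibility_state(net),
                         signal_mode = "offline")$elig
    expect_lt(max_rel_dev(e1$gW_in, e2$gW_in), 1e-12)
    expect_lt(max_rel_dev(e1$gW_out, e2$gW_out), 1e-12)
    if (flavor != "none")
      expect_lt(max_rel_dev(e1$gD_in, e2$gD_in), 1e-12)
  }
})

test_that("apply_updates: descent step, delay clamping, mask protection", {
  sim <- sim_params()
  R <- delay_half_range(sim)
  net <- network_params(W_in = matrix(1, 1, 2), W_out = matrix(0.5, 1, 1),
                        D_in = matrix(c(0, R), 1, 2),
                        flavor_in = "synaptic")
  elig <- eligibility_state(net)
  # zero gradients: parameters unchanged
  un <- apply_updates(net, elig, learn_rates(), sim)$net
  expect_equal(un$W_in, net$W_in)
  expect_equal(un$D_in, net$D_in)
  # hand gradient: lr_d = 1e-2, grad 1 at d = 0 -> -0.01; upper clamp holds
  elig$gD_in <- matrix(c(1, -5), 1, 2)
  elig$n_seq <- 1L
  up <- apply_updates(net, elig, learn_rates(), sim)$net
  expect_equal(up$D_in[1, 1], -0.01)
  expect_equal(up$D_in[1, 2], R)     # pushed past the bound, stays at it
  # masked weights and their delays stay untouched
  mask <- matrix(c(1, 0), 2, 2)
  netm <- init_network(2, 2, 2, sim, flavor_in = "synaptic", seed = 4)
  netm <- network_params(netm$W_in, netm$W_out, D_in = netm$D_in,
                         flavor_in = "synaptic", mask_in = mask)
  eg <- eligibility_state(netm)
  eg$gW_in <- matrix(1, 2, 2); eg$gD_in <- matrix(1, 2, 2); eg$n_seq <- 1L
  upm <- apply_updates(netm, eg, learn_rates(lr_w = 0.1, lr_d = 0.1), sim)$net
  expect_equal(upm$W_in[mask == 0], c(0, 0))
  expect_equal(upm$D_in[mask == 0], netm$D_in[mask == 0])
  expect_false(any(upm$W_in[mask == 1] == netm$W_in[mask == 1]))
})

test_that("masked synapses have permanently zero eligibility and gradients", {
  sim <- sim_params()
  set.seed(19)
  x <- random_raster(30, 5)
  mask <- make_sparsity_mask(c(4, 5), 0.5, seed = 2)
  net <- init_network(5, 4, 2, sim, flavor_in = "synaptic", seed = 9)
  net <- network_params(net$W_in * 6, net$W_out, D_in = net$D_in,
                        flavor_in = "synaptic", mask_in = mask)
  e <- train_sequence(x, 1L, net, sim, eligibility_state(net))$elig
  expect_true(all(e$gW_in[mask == 0] == 0))
  expect_true(all(e$gD_in[mask == 0] == 0))
})
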
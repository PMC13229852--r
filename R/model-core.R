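#' Map a continuous delay parameter to the integer delay used in simulation
#'
#' Continuous delay parameters live in `[-(D_max-1)/2, +(D_max-1)/2]`; the
#' lower bound represents no delay and the upper bound the maximum delay.
#' The forward simulation only ever uses the rounded, clipped integer
#' `round(d + (D_max-1)/2)` in `[0, D_max-1]` (round half up; clipping
#' absorbs out-of-range inputs).
#'
#' @param d continuous delay parameter(s).
#' @param D_max maximum delay in steps.
#' @return integer effective delay(s) in `[0, D_max-1]`, same shape as `d`.
#' @examples
#' effective_delay(-12, 25)  # 0  (no delay)
#' effective_delay(12, 25)   # 24 (maximum delay)
#' effective_delay(0, 25)    # 12 (midpoint)
#' @export
effective_delay <- function(d, D_max) {
  out <- clamp(round_half_up(d + (D_max - 1) / 2), 0, D_max - 1)
  storage.mode(out) <- "integer"
  out
}

#' Network parameters: weights, delays, masks, delay flavors
#'
#' Container for a single-hidden-layer network. Delay "flavor" per
#' projection is one of `"none"` (no delay parameters), `"axonal"` (one
#' shared continuous delay per presynaptic neuron) or `"synaptic"` (one
#' continuous delay per connection). The readout projection never carries
#' delays. Masked weight entries are forced to exactly zero.
#'
#' @param W_in `n_hidden x n_in` input weight matrix.
#' @param W_out `n_out x n_hidden` readout weight matrix.
#' @param W_rec optional `n_hidden x n_hidden` recurrent weight matrix;
#'   its diagonal is forced to zero.
#' @param D_in,D_rec continuous delay parameters for the input/recurrent
#'   projection: a vector of length `n_in` (`n_hidden` for recurrent) for
#'   the axonal flavor, a matrix matching the weight matrix for the
#'   synaptic flavor, or `NULL` for flavor `"none"`.
#' @param flavor_in,flavor_rec delay flavor per projection.
#' @param mask_in,mask_rec optional fixed binary sparsity masks matching
#'   the weight matrices.
#' @return An object of class `network_params`.
#' @export
network_params <- function(W_in, W_out, W_rec = NULL,
                           D_in = NULL, D_rec = NULL,
                           flavor_in = c("none", "axonal", "synaptic"),
                           flavor_rec = c("none", "axonal", "synaptic"),
                           mask_in = NULL, mask_rec = NULL) {
  flavor_in <- match.arg(flavor_in); flavor_rec <- match.arg(flavor_rec)
  W_in <- as.matrix(W_in); W_out <- as.matrix(W_out)
  n_hidden <- nrow(W_in); n_in <- ncol(W_in)
  if (ncol(W_out) != n_hidden)
    stop("ncol(W_out) must equal nrow(W_in) (hidden size)")
  if (!is.null(W_rec)) {
    W_rec <- as.matrix(W_rec)
    if (!all(dim(W_rec) == n_hidden)) stop("W_rec must be n_hidden x n_hidden")
    diag(W_rec) <- 0
  }
  check_delay <- function(D, flavor, n_pre, what) {
    if (flavor == "none") {
      if (!is.null(D)) stop(sprintf("%s given but flavor is 'none'", what))
      return(NULL)
    }
    if (is.null(D)) stop(sprintf("%s required for flavor '%s'", what, flavor))
    if (flavor == "axonal") {
      D <- as.numeric(D)
      if (length(D) != n_pre)
        stop(sprintf("axonal %s must have length %d", what, n_pre))
    } else {
      D <- as.matrix(D)
      if (nrow(D) != n_hidden || ncol(D) != n_pre)
        stop(sprintf("synaptic %s must be n_hidden x %d", what, n_pre))
    }
    D
  }
  D_in <- check_delay(D_in, flavor_in, n_in, "D_in")
  D_rec <- if (is.null(W_rec)) NULL
           else check_delay(D_rec, flavor_rec, n_hidden, "D_rec")
  if (!is.null(mask_in)) {
    mask_in <- as.matrix(mask_in)
    if (!all(dim(mask_in) == dim(W_in))) stop("mask_in shape mismatch")
    W_in <- W_in * mask_in
  }
  if (!is.null(mask_rec) && !is.null(W_rec)) {
    mask_rec <- as.matrix(mask_rec)
    if (!all(dim(mask_rec) == dim(W_rec))) stop("mask_rec shape mismatch")
    W_rec <- W_rec * mask_rec
  }
  structure(list(W_in = W_in, W_rec = W_rec, W_out = W_out,
                 D_in = D_in, D_rec = D_rec,
                 mask_in = mask_in, mask_rec = mask_rec,
                 flavor_in = flavor_in,
                 flavor_rec = if (is.null(W_rec)) "none" else flavor_rec,
                 n_in = n_in, n_hidden = n_hidden, n_out = nrow(W_out)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("network_params: %d -> %d%s -> %d\n", x$n_in, x$n_hidden,
              if (is.null(x$W_rec)) "" else " (recurrent)", x$n_out))
  cat(sprintf("  delay flavor: input=%s recurrent=%s\n",
              x$flavor_in, x$flavor_rec))
  if (!is.null(x$mask_in))
    cat(sprintf("  input density: %.3f\n", mean(x$mask_in)))
  invisible(x)
}

#' Initialize a network with seeded random weights and delays
#'
#' Weights are zero-mean uniform scaled by `1/sqrt(fan-in)`; continuous
#' delays are drawn uniformly over the legal range (or started at a fixed
#' point). No bias terms are used anywhere.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param sim a [sim_params()] object.
#' @param recurrent add a recurrent projection (zero diagonal).
#' @param flavor_in,flavor_rec delay flavor per projection.
#' @param density_in,density_rec connection density for the fixed random
#'   binary sparsity masks (1 = dense).
#' @param delay_init `"uniform"` draws continuous delays uniformly over
#'   the legal range; `"integer"` draws integer delay steps uniformly (the
#'   fixed-delay control condition); `"midpoint"` starts every delay at the
#'   center of the range; `"none"` starts every delay at the no-delay
#'   bound.
#' @param seed integer RNG seed.
#' @return a [network_params()] object.
#' @export
init_network <- function(n_in, n_hidden, n_out, sim = sim_params(),
                         recurrent = FALSE,
                         flavor_in = "synaptic", flavor_rec = "none",
                         density_in = 1, density_rec = 1,
                         delay_init = c("uniform", "integer", "midpoint",
                                        "none"),
                         seed = 1L) {
  delay_init <- match.arg(delay_init)
  set.seed(seed)
  R <- delay_half_range(sim)
  rw <- function(n_row, n_col, fan) {
    a <- 1 / sqrt(fan)
    matrix(stats::runif(n_row * n_col, -a, a), n_row, n_col)
  }
  rd <- function(n) switch(delay_init,
    uniform  = stats::runif(n, -R, R),
    integer  = sample.int(2 * R + 1, n, replace = TRUE) - 1 - R,
    midpoint = rep(0, n),
    none     = rep(-R, n))
  W_in <- rw(n_hidden, n_in, n_in)
  W_out <- rw(n_out, n_hidden, n_hidden)
  mask_in <- if (density_in < 1)
    make_sparsity_mask(c(n_hidden, n_in), density_in) else NULL
  W_rec <- NULL; mask_rec <- NULL
  if (recurrent) {
    W_rec <- rw(n_hidden, n_hidden, n_hidden)
    if (density_rec < 1)
      mask_rec <- make_sparsity_mask(c(n_hidden, n_hidden), density_rec)
  }
  D_in <- switch(flavor_in, none = NULL, axonal = rd(n_in),
                 synaptic = matrix(rd(n_hidden * n_in), n_hidden, n_in))
  D_rec <- if (recurrent)
    switch(flavor_rec, none = NULL, axonal = rd(n_hidden),
           synaptic = matrix(rd(n_hidden * n_hidden), n_hidden, n_hidden))
  network_params(W_in, W_out, W_rec, D_in, D_rec,
                 flavor_in = flavor_in,
                 flavor_rec = if (recurrent) flavor_rec else "none",
                 mask_in = mask_in, mask_rec = mask_rec)
}

# --- internal delay bookkeeping -------------------------------------------

# continuous, clamped shift values (>= 0) for a projection; NULL for "none"
delay_shifts <- function(net, sim, which = c("in", "rec")) {
  which <- match.arg(which)
  D <- if (which == "in") net$D_in else net$D_rec
  if (is.null(D)) return(NULL)
  R <- delay_half_range(sim)
  clamp(D, -R, R) + R
}

# integer effective delays; 0 (scalar) for flavor "none"
delay_integers <- function(net, sim, which = c("in", "rec")) {
  which <- match.arg(which)
  D <- if (which == "in") net$D_in else net$D_rec
  if (is.null(D)) return(0L)
  effective_delay(D, sim$D_max)
}

# expand per-projection effective delays to a full n_post x n_pre matrix
deff_matrix <- function(net, sim, which = c("in", "rec")) {
  which <- match.arg(which)
  n_pre <- if (which == "in") net$n_in else net$n_hidden
  de <- delay_integers(net, sim, which)
  if (length(de) == 1L) de <- rep(de, n_pre)
  if (is.null(dim(de))) de <- matrix(de, net$n_hidden, n_pre, byrow = TRUE)
  de
}

#' Fresh neuron state
#'
#' Membrane potentials, spikes, readout potentials and the delay ring
#' buffers, all zero-initialized (no spikes before t = 0).
#'
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(net, sim) {
  structure(list(v = numeric(net$n_hidden), z = numeric(net$n_hidden),
                 y = numeric(net$n_out),
                 in_buffer = matrix(0, net$n_in, sim$D_max),
                 rec_buffer = matrix(0, net$n_hidden, sim$D_max),
                 t = 0L),
            class = "neuron_state")
}

# weighted delayed drive from a ring buffer (column u+1 holds the signal
# u steps ago); W and deff are n_post x n_pre
buffer_drive <- function(W, deff, buffer) {
  out <- numeric(nrow(W))
  for (u in unique(as.vector(deff))) {
    Wu <- W * (deff == u)
    out <- out + Wu %*% buffer[, u + 1L]
  }
  as.vector(out)
}

#' Advance the hidden layer by one step
#'
#' `lif_step()` implements the feedforward membrane update
#' \deqn{v^{t+1} = \alpha v^t + \sum_i W_{ji} x_i^{t-D_{ji}} - z^t v_{th}}
#' with soft reset by threshold subtraction, followed by the strict
#' threshold `z = H(v > v_th)`. Delayed inputs are fetched from the input
#' ring buffer at each synapse's integer effective delay. `srnn_step()`
#' additionally adds the recurrent drive
#' \eqn{\sum_i W^{rec}_{ji} z_i^{t-D^{rec}_{ji}-1}} (one mandatory step of
#' recurrence latency plus the learned delay) and requires `W_rec`.
#'
#' @param state a [neuron_state()].
#' @param x_t input spike vector at the current step (length `n_in`).
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @return the updated `neuron_state` (readout `y` untouched; see
#'   [readout_step()]).
#' @export
lif_step <- function(state, x_t, net, sim) {
  step_core(state, x_t, net, sim, recurrent = FALSE)
}

#' @rdname lif_step
#' @export
srnn_step <- function(state, x_t, net, sim) {
  if (is.null(net$W_rec)) stop("`srnn_step()` requires `W_rec`")
  step_core(state, x_t, net, sim, recurrent = TRUE)
}

step_core <- function(state, x_t, net, sim, recurrent) {
  x_t <- as.numeric(x_t)
  if (length(x_t) != net$n_in)
    stop("input spike vector length does not match the input weight columns")
  D_max <- sim$D_max
  # recurrent drive uses z^{t-1-u}: column u+1 of the (not yet advanced)
  # recurrent buffer
  I_rec <- 0
  if (recurrent)
    I_rec <- buffer_drive(net$W_rec, deff_matrix(net, sim, "rec"),
                          state$rec_buffer)
  # advance the input buffer so column 1 is the current input (delay 0)
  state$in_buffer <- cbind(x_t, state$in_buffer[, -D_max, drop = FALSE],
                           deparse.level = 0)
  I_in <- buffer_drive(net$W_in, deff_matrix(net, sim, "in"),
                       state$in_buffer)
  v_new <- sim$alpha * state$v + I_in + I_rec - state$z * sim$v_th
  z_new <- as.numeric(v_new > sim$v_th)
  state$rec_buffer <- cbind(z_new, state$rec_buffer[, -D_max, drop = FALSE],
                            deparse.level = 0)
  state$v <- v_new
  state$z <- z_new
  state$t <- state$t + 1L
  state
}

#' Advance the readout layer by one step
#'
#' Leaky-integrator readout without threshold, reset or delays:
#' `y <- kappa * y + W_out %*% z`, using the hidden spikes of the current
#' step.
#'
#' @inheritParams lif_step
#' @return the updated `neuron_state`.
#' @export
readout_step <- function(state, net, sim) {
  state$y <- as.vector(sim$kappa * state$y + net$W_out %*% state$z)
  state
}

# --- vectorized forward pass ----------------------------------------------

# Extended signal matrix: D_max history rows (from a ring buffer, oldest
# first) stacked on top of the T new rows, so row D_max + t - u is the
# signal u steps before step t.
extend_history <- function(buffer, new_rows) {
  hist <- t(buffer[, ncol(buffer):1, drop = FALSE])
  rbind(hist, new_rows)
}

# Input current time series (T x n_hidden) from the extended raster.
projection_currents <- function(xext, W, deff, Tn, D_max) {
  out <- matrix(0, Tn, nrow(W))
  for (u in unique(as.vector(deff))) {
    Wu <- W * (deff == u)
    rows <- (D_max + 1L - u):(D_max + Tn - u)
    out <- out + xext[rows, , drop = FALSE] %*% t(Wu)
  }
  out
}

#' Run the full forward pass over a spike raster
#'
#' Simulates the delayed LIF hidden layer and the leaky-integrator
#' readout over all `T` steps, applies a softmax to the readout
#' potentials at every step and, when a label is supplied, computes the
#' cross-entropy loss \eqn{E = -\sum_t \log \hat\pi^t_{k^*}}. The
#' predicted label is the argmax over the time-summed softmax outputs.
#' The forward pass is strictly binary: no kernel smoothing enters it.
#'
#' @param raster a [spike_raster()] (or bare binary matrix).
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @param label optional 1-based true class; enables the loss.
#' @param state optional [neuron_state()] carried over from a previous
#'   chunk; defaults to the zero state.
#' @return An object of class `trajectory`: per-step matrices `v`, `z`,
#'   `y`, `pi_hat`, per-step `loss`, total loss `E`, predicted label
#'   `pred`, and the final `state` (for chunked simulation).
#' @export
forward_pass <- function(raster, net, sim, label = NULL, state = NULL) {
  x <- if (inherits(raster, "spike_raster")) raster$spikes else as.matrix(raster)
  Tn <- nrow(x)
  if (ncol(x) != net$n_in)
    stop("raster channel count does not match the input weight columns")
  if (!is.null(label) && (label < 1L || label > net$n_out))
    stop("`label` outside [1, n_out]")
  if (is.null(state)) state <- neuron_state(net, sim)
  D_max <- sim$D_max
  recurrent <- !is.null(net$W_rec)

  xext <- extend_history(state$in_buffer, x)
  Iin <- projection_currents(xext, net$W_in, deff_matrix(net, sim, "in"),
                             Tn, D_max)

  n_h <- net$n_hidden
  v <- matrix(0, Tn, n_h); z <- matrix(0, Tn, n_h)
  y <- matrix(0, Tn, net$n_out)
  vt <- state$v; zt <- state$z; yt <- state$y
  if (recurrent) {
    deff_rec <- deff_matrix(net, sim, "rec")
    u_rec <- unique(as.vector(deff_rec))
    W_rec_u <- lapply(u_rec, function(u) net$W_rec * (deff_rec == u))
    zext <- extend_history(state$rec_buffer, matrix(0, Tn, n_h))
  }
  for (t in seq_len(Tn)) {
    I_rec <- 0
    if (recurrent) {
      I_rec <- numeric(n_h)
      for (k in seq_along(u_rec)) {
        # z^{t-1-u}: row D_max + t - 1 - u of the extended spike history
        I_rec <- I_rec + W_rec_u[[k]] %*% zext[D_max + t - 1L - u_rec[k], ]
      }
      I_rec <- as.vector(I_rec)
    }
    vt <- sim$alpha * vt + Iin[t, ] + I_rec - zt * sim$v_th
    zt <- as.numeric(vt > sim$v_th)
    yt <- as.vector(sim$kappa * yt + net$W_out %*% zt)
    v[t, ] <- vt; z[t, ] <- zt; y[t, ] <- yt
    if (recurrent) zext[D_max + t, ] <- zt
  }
  pi_hat <- softmax_rows(y)
  loss <- if (is.null(label)) NULL else -log(pi_hat[, label])
  if (!recurrent) zext <- extend_history(state$rec_buffer, z)
  final <- structure(list(
    v = vt, z = zt, y = yt,
    in_buffer = t(xext[(D_max + Tn):(Tn + 1L), , drop = FALSE]),
    rec_buffer = t(zext[(D_max + Tn):(Tn + 1L), , drop = FALSE]),
    t = state$t + Tn), class = "neuron_state")
  structure(list(v = v, z = z, y = y, pi_hat = pi_hat, loss = loss,
                 E = if (is.null(loss)) NULL else sum(loss),
                 pred = which.max(colSums(pi_hat)), label = label,
                 state = final),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d steps, %d hidden spikes, pred=%d%s\n",
              nrow(x$z), sum(x$z), x$pred,
              if (is.null(x$E)) "" else sprintf(", E=%.4f", x$E)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the network parameters,
#' simulation parameters and the RNG state.
#'
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @param path file path.
#' @export
write_checkpoint <- function(net, sim, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(net = net, sim = sim, rng = rng), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
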
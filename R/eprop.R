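# Online three-factor learning of weights and delays.
#
# Every parameter update is the product of (i) a per-parameter eligibility
# trace built from strictly local quantities and (ii) a top-down learning
# signal from the readout error. Delay eligibilities use the Gaussian
# delay-derivative kernel as the drive; the forward pass stays binary.

#' Learning rates and batch size
#'
#' @param lr_w weight step size (default 1e-4).
#' @param lr_d delay step size (default 1e-2).
#' @param batch_size sequences accumulated per parameter update
#'   (default 16).
#' @return an object of class `learn_rates`.
#' @export
learn_rates <- function(lr_w = 1e-4, lr_d = 1e-2, batch_size = 16L) {
  stopifnot(lr_w >= 0, lr_d >= 0, batch_size >= 1)
  structure(list(lr_w = lr_w, lr_d = lr_d,
                 batch_size = as.integer(batch_size)),
            class = "learn_rates")
}

#' Which parameter groups are learnable
#'
#' Independent flags per group, matching the fixed-vs-learnable control
#' conditions (e.g. fixed random delays with learned weights, or delay
#' learning with frozen weights).
#'
#' @param w_in,w_rec,w_out,d_in,d_rec logical flags.
#' @return a named list of flags.
#' @export
learn_flags <- function(w_in = TRUE, w_rec = TRUE, w_out = TRUE,
                        d_in = TRUE, d_rec = TRUE) {
  list(w_in = w_in, w_rec = w_rec, w_out = w_out, d_in = d_in, d_rec = d_rec)
}

#' Eligibility state: gradient accumulators for one update batch
#'
#' Holds the per-parameter gradient accumulators that [train_sequence()]
#' adds into and [apply_updates()] consumes. The per-step low-pass traces
#' themselves live inside the per-sequence sweep and are reset between
#' sequences; masked entries never contribute.
#'
#' @param net a [network_params()] object.
#' @return an object of class `eligibility_state` with zeroed accumulators
#'   `gW_in`, `gW_rec`, `gW_out`, `gD_in`, `gD_rec`, a sequence counter
#'   `n_seq` and a running `loss_sum`.
#' @export
eligibility_state <- function(net) {
  zeros_like <- function(x) if (is.null(x)) NULL else x * 0
  structure(list(gW_in = net$W_in * 0,
                 gW_rec = zeros_like(net$W_rec),
                 gW_out = net$W_out * 0,
                 gD_in = zeros_like(net$D_in),
                 gD_rec = zeros_like(net$D_rec),
                 n_seq = 0L, loss_sum = 0),
            class = "eligibility_state")
}

#' Top-down learning signal
#'
#' The per-hidden-neuron error signal
#' \eqn{L_j^t = \sum_k W^{out}_{kj}(\hat\pi_k^{t'} - \pi^*_k)} derived from
#' the cross-entropy loss. In `"online"` mode the signal is instantaneous
#' (the \eqn{\kappa^{t'-t}} filtering of the readout leak is absorbed into
#' \eqn{\kappa}-filtered eligibility traces — the standard online
#' factorization); `"offline"` mode evaluates the acausal sum
#' \eqn{\sum_{t' \ge t} \kappa^{t'-t}(\hat\pi^{t'}-\pi^*)} literally, for
#' oracle comparisons. The two yield identical total gradients.
#'
#' @param pi_hat `T x n_out` matrix of per-step softmax outputs.
#' @param label 1-based true class.
#' @param W_out readout weight matrix (`n_out x n_hidden`).
#' @param kappa readout decay (used by `"offline"` mode).
#' @param mode `"online"` or `"offline"`.
#' @return `T x n_hidden` matrix of learning signals.
#' @export
learning_signal <- function(pi_hat, label, W_out, kappa,
                            mode = c("online", "offline")) {
  mode <- match.arg(mode)
  mu <- pi_hat
  mu[, label] <- mu[, label] - 1
  if (mode == "offline") mu <- kappa_future_filter(mu, kappa)
  mu %*% W_out
}

# Lam[t, ] = mu[t, ] + kappa * Lam[t+1, ]  (acausal smoothing of Eq-9 type)
kappa_future_filter <- function(mu, kappa) {
  Tn <- nrow(mu)
  out <- mu
  if (Tn > 1L) for (t in (Tn - 1L):1L) out[t, ] <- mu[t, ] + kappa * out[t + 1L, ]
  out
}

# --- per-sequence precomputation ------------------------------------------

# Delayed binary inputs, input currents and Gaussian delay-derivative
# drive traces for one raster. Shared by the online rules and the
# locality-matched oracle (the kernel arithmetic is common; the gradient
# accumulation schemes differ).
seq_precompute <- function(x, net, sim, need_drive = TRUE) {
  Tn <- nrow(x); D_max <- sim$D_max
  pre <- list(Tn = Tn)
  xext <- rbind(matrix(0, D_max, net$n_in), x)
  deff_in <- deff_matrix(net, sim, "in")
  pre$Iin <- projection_currents(xext, net$W_in, deff_in, Tn, D_max)

  # delayed presynaptic inputs for the weight eligibilities
  if (net$flavor_in == "synaptic") {
    XD <- array(0, c(Tn, net$n_hidden, net$n_in))
    for (i in seq_len(net$n_in)) {
      for (u in unique(deff_in[, i])) {
        rows <- which(deff_in[, i] == u)
        XD[, rows, i] <- matrix(shift_vec(x[, i], u),
                                Tn, length(rows))
      }
    }
    pre$XD <- XD
  } else {
    de <- delay_integers(net, sim, "in")
    if (length(de) == 1L) de <- rep(de, net$n_in)
    pre$XD <- vapply(seq_len(net$n_in),
                     function(i) shift_vec(x[, i], de[i]), numeric(Tn))
    if (Tn == 1L) pre$XD <- matrix(pre$XD, 1L)
  }

  # Gaussian delay-derivative drive traces (continuous shifts)
  if (need_drive && net$flavor_in != "none") {
    sh <- delay_shifts(net, sim, "in")
    if (net$flavor_in == "axonal") {
      pre$GP <- vapply(seq_len(net$n_in), function(i)
        kernel_column_trace(x[, i], sh[i], sim, deriv = TRUE), numeric(Tn))
      if (Tn == 1L) pre$GP <- matrix(pre$GP, 1L)
    } else {
      GP <- array(0, c(Tn, net$n_hidden, net$n_in))
      for (i in seq_len(net$n_in)) {
        for (cu in unique(sh[, i])) {
          rows <- which(sh[, i] == cu)
          GP[, rows, i] <- matrix(
            kernel_column_trace(x[, i], cu, sim, deriv = TRUE),
            Tn, length(rows))
        }
      }
      pre$GP <- GP
    }
  }

  if (!is.null(net$W_rec)) {
    deff_rec <- deff_matrix(net, sim, "rec")
    u_rec <- sort(unique(as.vector(deff_rec)))
    pre$u_rec <- u_rec
    pre$W_rec_u <- lapply(u_rec, function(u) net$W_rec * (deff_rec == u))
    pre$deff_rec <- deff_rec
    if (need_drive && net$flavor_rec != "none") {
      shr <- delay_shifts(net, sim, "rec")
      if (net$flavor_rec == "axonal")
        shr <- matrix(shr, net$n_hidden, net$n_hidden, byrow = TRUE)
      half <- sim$kernel_k / 2
      Lmax <- min(Tn - 1L, floor(max(shr) + half))
      lags <- 0L:Lmax
      WGd <- lapply(lags, function(L)
        net$W_rec * gaussian_delay_derivative(L - shr, sim$sigma,
                                              sim$kernel_k))
      keep <- vapply(WGd, function(m) any(m != 0), logical(1L))
      pre$rec_lags <- lags[keep]
      pre$rec_WGd <- WGd[keep]
    }
  }
  pre
}

shift_vec <- function(v, u) {
  if (u == 0L) return(v)
  n <- length(v)
  c(numeric(min(u, n)), v[seq_len(max(0L, n - u))])
}

# --- the online sweep ------------------------------------------------------

#' Train on one sequence: forward dynamics plus online gradient accumulation
#'
#' A single sweep over the sequence computing, at every step, the binary
#' forward dynamics, the surrogate derivatives, the learning signal, the
#' eligibility-trace recursions and the gradient accumulation. In
#' `"online"` mode only causally available information is used (the
#' readout-leak filtering is carried by \eqn{\kappa}-filtered traces); in
#' `"offline"` mode the acausal learning signal is evaluated literally
#' (used by the oracle tests; total gradients are identical).
#'
#' @param raster a [spike_raster()] or binary matrix.
#' @param label 1-based true class.
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @param elig an [eligibility_state()]; gradients are added into it.
#' @param learn a [learn_flags()] list.
#' @param signal_mode `"online"` or `"offline"`.
#' @return list with the updated `elig`, the sequence `loss` and the
#'   predicted label `pred`.
#' @export
train_sequence <- function(raster, label, net, sim, elig,
                           learn = learn_flags(),
                           signal_mode = c("online", "offline")) {
  signal_mode <- match.arg(signal_mode)
  x <- if (inherits(raster, "spike_raster")) raster$spikes else as.matrix(raster)
  Tn <- nrow(x)
  if (label < 1L || label > net$n_out) stop("`label` outside [1, n_out]")
  recurrent <- !is.null(net$W_rec)
  need_din <- isTRUE(learn$d_in) && net$flavor_in != "none"
  need_drec <- recurrent && isTRUE(learn$d_rec) && net$flavor_rec != "none"
  pre <- seq_precompute(x, net, sim, need_drive = need_din || need_drec)

  n_h <- net$n_hidden; n_in <- net$n_in; n_out <- net$n_out
  alpha <- sim$alpha; kappa <- sim$kappa; v_th <- sim$v_th
  syn_in <- net$flavor_in == "synaptic"
  syn_rec <- recurrent && net$flavor_rec == "synaptic"

  # offline-exact mode: the learning signal needs the future, so run the
  # dynamics first and filter the readout error backward in time; the
  # trace filter kappa is then dropped (set to 0) — same total gradient.
  Lmat <- NULL; trace_kappa <- kappa
  if (signal_mode == "offline") {
    fp <- forward_pass(x, net, sim, label = label)
    Lmat <- learning_signal(fp$pi_hat, label, net$W_out, kappa, "offline")
    Lam_out <- kappa_future_filter(
      {m <- fp$pi_hat; m[, label] <- m[, label] - 1; m}, kappa)
    trace_kappa <- 0
  }

  # dynamic state
  vt <- numeric(n_h); zprev <- numeric(n_h); yt <- numeric(n_out)
  zhist <- matrix(0, Tn, n_h)
  # eligibility traces (reset at sequence start by construction)
  if (learn$w_out) { zbar <- numeric(n_h); gW_out <- elig$gW_out * 0 }
  if (learn$w_in) {
    ebarW <- matrix(0, n_h, n_in)
    epsW <- if (syn_in) matrix(0, n_h, n_in) else NULL
    fx <- if (!syn_in) numeric(n_in) else NULL
    gW_in <- net$W_in * 0
  }
  if (need_din) {
    ebarD <- matrix(0, n_h, n_in)
    epsD <- if (syn_in) matrix(0, n_h, n_in) else NULL
    gax <- if (!syn_in) numeric(n_in) else NULL
    gD_in <- net$D_in * 0
  }
  if (recurrent && learn$w_rec) {
    ebarWr <- matrix(0, n_h, n_h)
    epsWr <- matrix(0, n_h, n_h)  # delayed z can differ per synapse
    gW_rec <- net$W_rec * 0
  }
  if (need_drec) {
    ebarDr <- matrix(0, n_h, n_h)
    epsDr <- matrix(0, n_h, n_h)
    gD_rec <- net$D_rec * 0
  }
  loss <- 0; pi_sum <- numeric(n_out)

  for (t in seq_len(Tn)) {
    # --- forward dynamics (binary) ---
    I_rec <- 0
    if (recurrent) {
      I_rec <- numeric(n_h)
      for (k in seq_along(pre$u_rec)) {
        tr <- t - 1L - pre$u_rec[k]
        if (tr >= 1L) I_rec <- I_rec + pre$W_rec_u[[k]] %*% zhist[tr, ]
      }
      I_rec <- as.vector(I_rec)
    }
    vt <- alpha * vt + pre$Iin[t, ] + I_rec - zprev * v_th
    znew <- as.numeric(vt > v_th)
    psi <- spike_surrogate(vt, v_th, sim$gamma_pd)
    yt <- as.vector(kappa * yt + net$W_out %*% znew)
    e <- exp(yt - max(yt)); pi_t <- e / sum(e)
    pi_sum <- pi_sum + pi_t
    loss <- loss - log(pi_t[label])
    mu <- pi_t; mu[label] <- mu[label] - 1
    l_t <- if (is.null(Lmat)) as.vector(crossprod(net$W_out, mu))
           else Lmat[t, ]

    # --- eligibility recursions and gradient accumulation ---
    if (learn$w_out) {
      zbar <- trace_kappa * zbar + znew
      mo <- if (is.null(Lmat)) mu else Lam_out[t, ]
      gW_out <- gW_out + outer(mo, zbar)
    }
    if (learn$w_in) {
      if (syn_in) {
        epsW <- alpha * epsW + matrix(pre$XD[t, , ], n_h, n_in)
        eW <- psi * epsW
      } else {
        fx <- alpha * fx + pre$XD[t, ]
        eW <- outer(psi, fx)
      }
      if (!is.null(net$mask_in)) eW <- eW * net$mask_in
      ebarW <- trace_kappa * ebarW + eW
      gW_in <- gW_in + l_t * ebarW
    }
    if (need_din) {
      if (syn_in) {
        epsD <- alpha * epsD + net$W_in * matrix(pre$GP[t, , ], n_h, n_in)
        eD <- psi * epsD
        if (!is.null(net$mask_in)) eD <- eD * net$mask_in
        ebarD <- trace_kappa * ebarD + eD
        gD_in <- gD_in + l_t * ebarD
      } else {
        gax <- alpha * gax + pre$GP[t, ]
        eD <- (psi * net$W_in) * rep(gax, each = n_h)
        ebarD <- trace_kappa * ebarD + eD
        gD_in <- gD_in + colSums(l_t * ebarD)
      }
    }
    if (recurrent && learn$w_rec) {
      # delayed presynaptic hidden spikes per synapse
      zd <- matrix(0, n_h, n_h)
      for (k in seq_along(pre$u_rec)) {
        tr <- t - 1L - pre$u_rec[k]
        if (tr >= 1L) {
          sel <- pre$deff_rec == pre$u_rec[k]
          zd[sel] <- rep(zhist[tr, ], each = n_h)[sel]
        }
      }
      epsWr <- alpha * epsWr + zd
      eWr <- psi * epsWr
      if (!is.null(net$mask_rec)) eWr <- eWr * net$mask_rec
      ebarWr <- trace_kappa * ebarWr + eWr
      gW_rec <- gW_rec + l_t * ebarWr
    }
    if (need_drec) {
      drv <- matrix(0, n_h, n_h)
      for (k in seq_along(pre$rec_lags)) {
        tr <- t - 1L - pre$rec_lags[k]
        if (tr >= 1L)
          drv <- drv + pre$rec_WGd[[k]] * rep(zhist[tr, ], each = n_h)
      }
      epsDr <- alpha * epsDr + drv
      eDr <- psi * epsDr
      if (!is.null(net$mask_rec)) eDr <- eDr * net$mask_rec
      ebarDr <- trace_kappa * ebarDr + eDr
      if (net$flavor_rec == "synaptic") {
        gD_rec <- gD_rec + l_t * ebarDr
      } else {
        gD_rec <- gD_rec + colSums(l_t * ebarDr)
      }
    }
    zhist[t, ] <- znew
    zprev <- znew
  }

  # fold this sequence's gradients into the batch accumulators
  if (learn$w_out) elig$gW_out <- elig$gW_out + gW_out
  if (learn$w_in) {
    if (!is.null(net$mask_in)) gW_in <- gW_in * net$mask_in
    elig$gW_in <- elig$gW_in + gW_in
  }
  if (need_din) {
    if (syn_in && !is.null(net$mask_in)) gD_in <- gD_in * net$mask_in
    elig$gD_in <- elig$gD_in + gD_in
  }
  if (recurrent && learn$w_rec) {
    if (!is.null(net$mask_rec)) gW_rec <- gW_rec * net$mask_rec
    diag(gW_rec) <- 0
    elig$gW_rec <- elig$gW_rec + gW_rec
  }
  if (need_drec) {
    if (syn_rec && !is.null(net$mask_rec)) gD_rec <- gD_rec * net$mask_rec
    if (syn_rec) diag(gD_rec) <- 0
    elig$gD_rec <- elig$gD_rec + gD_rec
  }
  elig$n_seq <- elig$n_seq + 1L
  elig$loss_sum <- elig$loss_sum + loss
  list(elig = elig, loss = loss, pred = which.max(pi_sum))
}

#' Apply accumulated updates to the network
#'
#' Plain gradient descent on the batch-mean gradients:
#' \eqn{\theta \gets \theta - \eta\,\bar g}. Continuous delays are clamped
#' to \eqn{[-(D_{max}-1)/2, +(D_{max}-1)/2]}; masked weights and their
#' delays are untouched; accumulators are cleared.
#'
#' @param net a [network_params()] object.
#' @param elig an [eligibility_state()] with accumulated gradients.
#' @param rates a [learn_rates()] object.
#' @param sim a [sim_params()] object.
#' @param learn a [learn_flags()] list.
#' @return list with the updated `net` and a cleared `elig`.
#' @export
apply_updates <- function(net, elig, rates, sim, learn = learn_flags()) {
  n <- max(elig$n_seq, 1L)
  R <- delay_half_range(sim)
  if (learn$w_in) {
    net$W_in <- net$W_in - rates$lr_w * elig$gW_in / n
    if (!is.null(net$mask_in)) net$W_in <- net$W_in * net$mask_in
  }
  if (learn$w_out)
    net$W_out <- net$W_out - rates$lr_w * elig$gW_out / n
  if (!is.null(net$W_rec) && learn$w_rec) {
    net$W_rec <- net$W_rec - rates$lr_w * elig$gW_rec / n
    if (!is.null(net$mask_rec)) net$W_rec <- net$W_rec * net$mask_rec
    diag(net$W_rec) <- 0
  }
  if (!is.null(net$D_in) && learn$d_in) {
    step <- rates$lr_d * elig$gD_in / n
    if (net$flavor_in == "synaptic" && !is.null(net$mask_in))
      step <- step * net$mask_in
    net$D_in <- clamp(net$D_in - step, -R, R)
  }
  if (!is.null(net$D_rec) && learn$d_rec) {
    step <- rates$lr_d * elig$gD_rec / n
    if (net$flavor_rec == "synaptic" && !is.null(net$mask_rec))
      step <- step * net$mask_rec
    net$D_rec <- clamp(net$D_rec - step, -R, R)
  }
  list(net = net, elig = eligibility_state(net))
}
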
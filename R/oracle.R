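# Brute-force unrolled gradient references.
#
# Two modes:
#   "locality_matched": reverse-mode differentiation of the binary forward
#     pass with the same local substitutions as the online rules
#     (piecewise-linear surrogate at thresholds, Gaussian delay derivative
#     for delay paths, reset and recurrent-spike credit detached). On
#     feedforward networks this equals the online three-factor gradients
#     exactly, up to floating-point summation order.
#   "full": exact reverse-mode gradient of a fully smooth relaxation of
#     the network (Gaussian-smoothed delayed spike trains everywhere a
#     delay parameter appears, and a C^1 spike function whose derivative
#     is exactly the piecewise-linear surrogate), propagating through the
#     reset and recurrent-spike paths. Because that relaxation is an
#     ordinary differentiable function, its gradient can be validated
#     against central finite differences — this pins down the delay
#     pathway independently of the online implementation.

#' Unrolled reference gradients
#'
#' @param raster a [spike_raster()] or binary matrix.
#' @param label 1-based true class.
#' @param net a [network_params()] object.
#' @param sim a [sim_params()] object.
#' @param mode `"locality_matched"` or `"full"` (see Details above).
#' @param max_T guard against accidentally unrolling very long sequences.
#' @return list of gradients `gW_in`, `gW_rec`, `gW_out`, `gD_in`,
#'   `gD_rec` (NULL where absent) and the loss `E` of the corresponding
#'   forward pass.
#' @export
unrolled_gradient <- function(raster, label, net, sim,
                              mode = c("locality_matched", "full"),
                              max_T = 2000L) {
  mode <- match.arg(mode)
  x <- if (inherits(raster, "spike_raster")) raster$spikes else as.matrix(raster)
  if (nrow(x) > max_T)
    stop(sprintf("sequence length %d exceeds the unrolled-oracle guard (%d)",
                 nrow(x), max_T))
  if (mode == "locality_matched") oracle_locality(x, label, net, sim)
  else oracle_full(x, label, net, sim)
}

# --- mode (a): binary forward, locality-matched backward ------------------

oracle_locality <- function(x, label, net, sim) {
  Tn <- nrow(x); n_h <- net$n_hidden
  pre <- seq_precompute(x, net, sim, need_drive = net$flavor_in != "none" ||
                          (!is.null(net$W_rec) && net$flavor_rec != "none"))
  fp <- forward_pass(x, net, sim, label = label)
  psi <- spike_surrogate(fp$v, sim$v_th, sim$gamma_pd)
  mu <- fp$pi_hat; mu[, label] <- mu[, label] - 1
  Lam <- kappa_future_filter(mu, sim$kappa)       # T x n_out
  Lmat <- Lam %*% net$W_out                       # T x n_hidden
  # delta v: alpha-chain only (reset and recurrent spike credit detached)
  dv <- psi * Lmat
  if (Tn > 1L) for (t in (Tn - 1L):1L) dv[t, ] <- dv[t, ] + sim$alpha * dv[t + 1L, ]

  out <- list(gW_in = NULL, gW_rec = NULL, gW_out = t(Lam) %*% fp$z,
              gD_in = NULL, gD_rec = NULL, E = fp$E)
  if (net$flavor_in == "synaptic") {
    gW <- net$W_in * 0; gD <- gW
    for (i in seq_len(net$n_in)) {
      gW[, i] <- colSums(dv * matrix(pre$XD[, , i], Tn, n_h))
      gD[, i] <- net$W_in[, i] * colSums(dv * matrix(pre$GP[, , i], Tn, n_h))
    }
    out$gW_in <- gW; out$gD_in <- gD
  } else {
    out$gW_in <- t(dv) %*% pre$XD
    if (net$flavor_in == "axonal")
      out$gD_in <- colSums((dv %*% net$W_in) * pre$GP)
  }
  if (!is.null(net$mask_in)) {
    out$gW_in <- out$gW_in * net$mask_in
    if (net$flavor_in == "synaptic") out$gD_in <- out$gD_in * net$mask_in
  }
  if (!is.null(net$W_rec)) {
    # lagged co-activation sums M_L[j,i] = sum_t dv[t,j] z[t-1-L, i]
    lag_M <- function(L) {
      if (Tn - 1L - L < 1L) return(matrix(0, n_h, n_h))
      crossprod(dv[(L + 2L):Tn, , drop = FALSE],
                fp$z[1L:(Tn - 1L - L), , drop = FALSE])
    }
    gWr <- matrix(0, n_h, n_h)
    for (k in seq_along(pre$u_rec)) {
      u <- pre$u_rec[k]
      gWr <- gWr + (pre$deff_rec == u) * lag_M(u)
    }
    if (!is.null(net$mask_rec)) gWr <- gWr * net$mask_rec
    diag(gWr) <- 0
    out$gW_rec <- gWr
    if (net$flavor_rec != "none") {
      shr <- delay_shifts(net, sim, "rec")
      if (net$flavor_rec == "axonal")
        shr <- matrix(shr, n_h, n_h, byrow = TRUE)
      half <- sim$kernel_k / 2
      Lmax <- min(Tn - 1L, floor(max(shr) + half))
      gDr <- matrix(0, n_h, n_h)
      for (L in 0L:Lmax) {
        gk <- gaussian_delay_derivative(L - shr, sim$sigma, sim$kernel_k)
        if (any(gk != 0)) gDr <- gDr + gk * lag_M(L)
      }
      gDr <- net$W_rec * gDr
      if (net$flavor_rec == "synaptic") {
        if (!is.null(net$mask_rec)) gDr <- gDr * net$mask_rec
        diag(gDr) <- 0
        out$gD_rec <- gDr
      } else {
        out$gD_rec <- colSums(gDr)
      }
    }
  }
  out
}

# --- mode (b): fully smooth relaxation ------------------------------------

# C^1 spike function whose derivative is exactly the piecewise-linear
# surrogate: S(v) ramps from 0 (v <= 0) to gamma_pd (v >= 2 v_th).
smooth_spike_fn <- function(v, v_th, gamma_pd) {
  s <- numeric(length(v))
  lo <- v > 0 & v <= v_th
  hi <- v > v_th & v < 2 * v_th
  s[lo] <- gamma_pd * v[lo]^2 / (2 * v_th^2)
  s[hi] <- gamma_pd * (1 - (2 * v_th - v[hi])^2 / (2 * v_th^2))
  s[v >= 2 * v_th] <- gamma_pd
  dim(s) <- dim(v)
  s
}

# Smoothed input drive structures for the relaxation.
smooth_input_traces <- function(x, net, sim, deriv = FALSE) {
  Tn <- nrow(x)
  if (net$flavor_in == "none") {
    if (deriv) return(NULL)
    return(x)                                   # binary, delay 0
  }
  sh <- delay_shifts(net, sim, "in")
  if (net$flavor_in == "axonal") {
    out <- vapply(seq_len(net$n_in), function(i)
      kernel_column_trace(x[, i], sh[i], sim, deriv = deriv), numeric(Tn))
    if (Tn == 1L) out <- matrix(out, 1L)
    out
  } else {
    out <- array(0, c(Tn, net$n_hidden, net$n_in))
    for (i in seq_len(net$n_in))
      for (cu in unique(sh[, i])) {
        rows <- which(sh[, i] == cu)
        out[, rows, i] <- matrix(
          kernel_column_trace(x[, i], cu, sim, deriv = deriv),
          Tn, length(rows))
      }
    out
  }
}

# recurrent lag-kernel matrices g(L - c_ji) (or derivative), L = 0..Lmax
rec_lag_kernels <- function(net, sim, Tn, deriv = FALSE) {
  shr <- delay_shifts(net, sim, "rec")
  n_h <- net$n_hidden
  if (net$flavor_rec == "none") {
    # plain one-step recurrence: kernel is a Kronecker delta at lag 0
    k0 <- if (deriv) matrix(0, n_h, n_h) else matrix(1, n_h, n_h)
    return(list(lags = 0L, mats = list(k0)))
  }
  if (net$flavor_rec == "axonal") shr <- matrix(shr, n_h, n_h, byrow = TRUE)
  half <- sim$kernel_k / 2
  Lmax <- min(Tn - 1L, floor(max(shr) + half))
  fn <- if (deriv) gaussian_delay_derivative else gaussian_spike
  lags <- 0L:Lmax
  mats <- lapply(lags, function(L) fn(L - shr, sim$sigma, sim$kernel_k))
  keep <- vapply(mats, function(m) any(m != 0), logical(1L))
  if (!any(keep)) return(list(lags = integer(0), mats = list()))
  list(lags = lags[keep], mats = mats[keep])
}

#' Smooth relaxed forward pass
#'
#' A fully differentiable relaxation of the network used by the `"full"`
#' oracle mode and by finite-difference checks: delayed spike trains are
#' replaced by their Gaussian-smoothed versions (continuous in the delay
#' parameters) and the threshold by a C\eqn{^1} spike function whose
#' derivative is the piecewise-linear surrogate. This function is for
#' gradient verification only — it never participates in simulation or
#' online learning.
#'
#' @inheritParams unrolled_gradient
#' @return list with the relaxed loss `E` and the per-step relaxed state
#'   (`v`, `z` (graded), `y`, `pi_hat`).
#' @export
smooth_forward <- function(raster, label, net, sim) {
  x <- if (inherits(raster, "spike_raster")) raster$spikes else as.matrix(raster)
  Tn <- nrow(x); n_h <- net$n_hidden
  recurrent <- !is.null(net$W_rec)
  Xs <- smooth_input_traces(x, net, sim, deriv = FALSE)
  Cin <- input_currents_smooth(Xs, net)
  if (recurrent) rk <- rec_lag_kernels(net, sim, Tn, deriv = FALSE)
  v <- matrix(0, Tn, n_h); zt <- matrix(0, Tn, n_h)
  y <- matrix(0, Tn, net$n_out)
  vt <- numeric(n_h); zp <- numeric(n_h); yt <- numeric(net$n_out)
  for (t in seq_len(Tn)) {
    I_rec <- 0
    if (recurrent && length(rk$lags)) {
      I_rec <- numeric(n_h)
      for (k in seq_along(rk$lags)) {
        tr <- t - 1L - rk$lags[k]
        if (tr >= 1L)
          I_rec <- I_rec + (net$W_rec * rk$mats[[k]]) %*% zt[tr, ]
      }
      I_rec <- as.vector(I_rec)
    }
    vt <- sim$alpha * vt + Cin[t, ] + I_rec - zp * sim$v_th
    zp <- smooth_spike_fn(vt, sim$v_th, sim$gamma_pd)
    yt <- as.vector(sim$kappa * yt + net$W_out %*% zp)
    v[t, ] <- vt; zt[t, ] <- zp; y[t, ] <- yt
  }
  pi_hat <- softmax_rows(y)
  list(E = -sum(log(pi_hat[, label])), v = v, z = zt, y = y,
       pi_hat = pi_hat)
}

input_currents_smooth <- function(Xs, net) {
  if (is.matrix(Xs)) return(Xs %*% t(net$W_in))
  Tn <- dim(Xs)[1L]
  Cin <- matrix(0, Tn, net$n_hidden)
  for (i in seq_len(net$n_in))
    Cin <- Cin + matrix(Xs[, , i], Tn, net$n_hidden) *
      rep(net$W_in[, i], each = Tn)
  Cin
}

oracle_full <- function(x, label, net, sim) {
  Tn <- nrow(x); n_h <- net$n_hidden
  recurrent <- !is.null(net$W_rec)
  sf <- smooth_forward(x, label, net, sim)
  Xs <- smooth_input_traces(x, net, sim, deriv = FALSE)
  XsD <- smooth_input_traces(x, net, sim, deriv = TRUE)
  if (recurrent) {
    rk <- rec_lag_kernels(net, sim, Tn, deriv = FALSE)
    rkD <- if (net$flavor_rec != "none")
      rec_lag_kernels(net, sim, Tn, deriv = TRUE) else NULL
  }
  psi <- spike_surrogate(sf$v, sim$v_th, sim$gamma_pd)
  mu <- sf$pi_hat; mu[, label] <- mu[, label] - 1
  dy <- kappa_future_filter(mu, sim$kappa)        # T x n_out
  base <- dy %*% net$W_out                        # T x n_hidden
  dv <- matrix(0, Tn, n_h); dz <- matrix(0, Tn, n_h)
  for (t in Tn:1L) {
    dzt <- base[t, ]
    if (t < Tn) dzt <- dzt - sim$v_th * dv[t + 1L, ]   # reset path
    if (recurrent && length(rk$lags)) {
      for (k in seq_along(rk$lags)) {
        tp <- t + 1L + rk$lags[k]
        if (tp <= Tn)
          dzt <- dzt + as.vector(
            crossprod(net$W_rec * rk$mats[[k]], dv[tp, ]))
      }
    }
    dvt <- psi[t, ] * dzt
    if (t < Tn) dvt <- dvt + sim$alpha * dv[t + 1L, ]
    dz[t, ] <- dzt; dv[t, ] <- dvt
  }
  out <- list(gW_in = NULL, gW_rec = NULL, gW_out = t(dy) %*% sf$z,
              gD_in = NULL, gD_rec = NULL, E = sf$E)
  if (net$flavor_in == "synaptic") {
    gW <- net$W_in * 0; gD <- gW
    for (i in seq_len(net$n_in)) {
      gW[, i] <- colSums(dv * matrix(Xs[, , i], Tn, n_h))
      gD[, i] <- net$W_in[, i] * colSums(dv * matrix(XsD[, , i], Tn, n_h))
    }
    out$gW_in <- gW; out$gD_in <- gD
  } else {
    out$gW_in <- t(dv) %*% Xs
    if (net$flavor_in == "axonal")
      out$gD_in <- colSums((dv %*% net$W_in) * XsD)
  }
  if (!is.null(net$mask_in)) {
    out$gW_in <- out$gW_in * net$mask_in
    if (net$flavor_in == "synaptic") out$gD_in <- out$gD_in * net$mask_in
  }
  if (recurrent) {
    lag_M <- function(L) {
      if (Tn - 1L - L < 1L) return(matrix(0, n_h, n_h))
      crossprod(dv[(L + 2L):Tn, , drop = FALSE],
                sf$z[1L:(Tn - 1L - L), , drop = FALSE])
    }
    gWr <- matrix(0, n_h, n_h)
    for (k in seq_along(rk$lags))
      gWr <- gWr + rk$mats[[k]] * lag_M(rk$lags[k])
    if (!is.null(net$mask_rec)) gWr <- gWr * net$mask_rec
    diag(gWr) <- 0
    out$gW_rec <- gWr
    if (net$flavor_rec != "none") {
      gDr <- matrix(0, n_h, n_h)
      for (k in seq_along(rkD$lags))
        gDr <- gDr + rkD$mats[[k]] * lag_M(rkD$lags[k])
      gDr <- net$W_rec * gDr
      if (net$flavor_rec == "synaptic") {
        if (!is.null(net$mask_rec)) gDr <- gDr * net$mask_rec
        diag(gDr) <- 0
        out$gD_rec <- gDr
      } else {
        out$gD_rec <- colSums(gDr)
      }
    }
  }
  out
}

#' Central finite differences of the smooth relaxed loss
#'
#' Perturbs one parameter entry of the network by \eqn{\pm h}, reruns
#' [smooth_forward()] and returns the central difference — the
#' independent check of the `"full"` oracle mode.
#'
#' @inheritParams unrolled_gradient
#' @param param one of `"W_in"`, `"W_rec"`, `"W_out"`, `"D_in"`,
#'   `"D_rec"`.
#' @param idx index (scalar position) into the parameter array.
#' @param h step size.
#' @return the finite-difference derivative estimate.
#' @export
fd_smooth_gradient <- function(raster, label, net, sim, param, idx,
                               h = 1e-3) {
  perturb <- function(delta) {
    net[[param]][idx] <- net[[param]][idx] + delta
    smooth_forward(raster, label, net, sim)$E
  }
  (perturb(h) - perturb(-h)) / (2 * h)
}

#' Compare online three-factor gradients against the unrolled oracle
#'
#' Runs the online rules (offline-exact learning-signal mode) and the
#' locality-matched unrolled oracle on one sequence and reports the
#' per-parameter-group maximum absolute and relative deviation (relative
#' to the largest gradient magnitude in the group).
#'
#' @inheritParams unrolled_gradient
#' @param learn a [learn_flags()] list.
#' @return data.frame with one row per parameter group.
#' @export
gradient_check <- function(raster, label, net, sim,
                           learn = learn_flags()) {
  elig <- eligibility_state(net)
  res <- train_sequence(raster, label, net, sim, elig, learn,
                        signal_mode = "offline")
  ora <- unrolled_gradient(raster, label, net, sim, "locality_matched")
  groups <- list(W_in = list(res$elig$gW_in, ora$gW_in),
                 W_rec = list(res$elig$gW_rec, ora$gW_rec),
                 W_out = list(res$elig$gW_out, ora$gW_out),
                 D_in = list(res$elig$gD_in, ora$gD_in),
                 D_rec = list(res$elig$gD_rec, ora$gD_rec))
  rows <- lapply(names(groups), function(g) {
    a <- groups[[g]][[1L]]; b <- groups[[g]][[2L]]
    if (is.null(a) || is.null(b)) return(NULL)
    scale <- max(abs(b), 1e-300)
    data.frame(group = g, max_abs = max(abs(a - b)),
               max_rel = max(abs(a - b)) / scale)
  })
  do.call(rbind, rows)
}
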
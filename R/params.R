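#' Simulation parameters for the discrete-time LIF network
#'
#' Bundles the timestep-level constants of the neuron and readout dynamics.
#' The membrane decay per step is \eqn{\alpha = e^{-\Delta t/\tau_m}} and the
#' readout decay is \eqn{\kappa = e^{-\Delta t/\tau_o}}; both must lie
#' strictly inside (0, 1). Delays are represented on an integer grid of
#' `D_max` steps; a continuous delay parameter `d` lives in
#' \eqn{[-(D_{max}-1)/2, +(D_{max}-1)/2]}, with the lower bound meaning
#' "no delay" and the upper bound the maximum delay.
#'
#' @param alpha membrane decay per step (default 0.6, i.e. the value
#'   \eqn{e^{-\Delta t/\tau_m}} used throughout the experiments).
#' @param kappa readout decay per step. Default `exp(-0.01)` \eqn{\approx}
#'   0.990, from \eqn{\tau_o = 1} s at a 10 ms timestep; the readout is a
#'   slow leaky integrator that effectively accumulates evidence over the
#'   whole sequence.
#' @param v_th firing threshold. The dynamics are invariant to a joint
#'   rescaling of `v_th` and the weights, so the conventional unit
#'   threshold is the default.
#' @param dt timestep duration in milliseconds (default 10).
#' @param D_max maximum delay in steps (default 25, i.e. 250 ms at 10 ms
#'   per step).
#' @param gamma_pd dampening of the piecewise-linear spike surrogate
#'   (default 0.3).
#' @param sigma width (in steps) of the Gaussian kernel used to smooth
#'   spike trains inside learning computations (default 2).
#' @param kernel_k tap count of the truncated Gaussian window (default 12);
#'   the kernel is evaluated on integer offsets `u` with `|u| <= kernel_k/2`
#'   and is zero outside.
#'
#' @return An object of class `sim_params`.
#' @examples
#' sp <- sim_params()
#' max_latency_ms(sp)  # 250
#' @export
sim_params <- function(alpha = 0.6, kappa = exp(-0.01), v_th = 1.0,
                       dt = 10, D_max = 25L, gamma_pd = 0.3,
                       sigma = 2, kernel_k = 12L) {
  stopifnot_scalar(alpha, "alpha"); stopifnot_scalar(kappa, "kappa")
  stopifnot_scalar(v_th, "v_th"); stopifnot_scalar(dt, "dt")
  stopifnot_scalar(sigma, "sigma")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (kappa <= 0 || kappa >= 1) stop("`kappa` must be in (0, 1)")
  D_max <- as.integer(D_max)
  if (D_max < 1L) stop("`D_max` must be >= 1")
  kernel_k <- as.integer(kernel_k)
  if (kernel_k < 1L || kernel_k > D_max)
    stop("`kernel_k` must be in [1, D_max]")
  structure(list(alpha = alpha, kappa = kappa, v_th = v_th, dt = dt,
                 D_max = D_max, gamma_pd = gamma_pd, sigma = sigma,
                 kernel_k = kernel_k),
            class = "sim_params")
}

#' Maximum representable latency in milliseconds
#'
#' @param sim a [sim_params()] object.
#' @return `D_max * dt`, the longest delay the integer grid can express.
#' @export
max_latency_ms <- function(sim) sim$D_max * sim$dt

#' Half-range of the continuous delay parameters
#'
#' Continuous delays are clamped to `[-delay_half_range(sim),
#' +delay_half_range(sim)]`; the lower end maps to an effective delay of 0
#' steps and the upper end to `D_max - 1` steps.
#' @param sim a [sim_params()] object.
#' @export
delay_half_range <- function(sim) (sim$D_max - 1) / 2

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: alpha=%.4g kappa=%.4g v_th=%.3g dt=%gms D_max=%d (max %g ms)\n",
    x$alpha, x$kappa, x$v_th, x$dt, x$D_max, max_latency_ms(x)))
  cat(sprintf("  surrogates: gamma_pd=%.3g sigma=%.3g kernel_k=%d\n",
              x$gamma_pd, x$sigma, x$kernel_k))
  invisible(x)
}
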
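# Surrogate functions used exclusively inside learning computations.
# The forward simulation is strictly binary; nothing here ever enters it.

#' Piecewise-linear spike surrogate derivative
#'
#' Smooth stand-in for the derivative of the Heaviside spike function with
#' respect to the membrane potential,
#' \deqn{\psi(v) = \frac{\gamma_{pd}}{v_{th}}\max\left(0,\; 1 -
#'   \left|\frac{v - v_{th}}{v_{th}}\right|\right),}
#' a triangular bump peaking at \eqn{v = v_{th}} with support
#' \eqn{(0, 2 v_{th})}.
#'
#' @param v membrane potential(s).
#' @param v_th firing threshold.
#' @param gamma_pd dampening factor (default 0.3).
#' @return surrogate derivative value(s), same shape as `v`.
#' @examples
#' spike_surrogate(1, v_th = 1)    # peak: 0.3
#' spike_surrogate(1.5, v_th = 1)  # 0.15
#' @export
spike_surrogate <- function(v, v_th = 1, gamma_pd = 0.3) {
  out <- (gamma_pd / v_th) * pmax(0, 1 - abs((v - v_th) / v_th))
  dim(out) <- dim(v)
  out
}

#' Truncated Gaussian spike kernel and its delay derivative
#'
#' `gaussian_spike()` evaluates the density-normalized Gaussian
#' \eqn{g(u) = \exp(-u^2/2\sigma^2)/(\sqrt{2\pi}\sigma)} that replaces a
#' unit spike during learning; `gaussian_delay_derivative()` evaluates its
#' derivative with respect to the delay parameter,
#' \eqn{+u\,\exp(-u^2/2\sigma^2)/(\sqrt{2\pi}\sigma^3)} (positive for
#' `u > 0`: increasing the delay moves the smoothed spike toward later
#' times). Both are truncated to the symmetric window `|u| <= kernel_k/2`
#' and are zero outside; truncation is plain windowing, without
#' renormalization.
#'
#' @param u time offset(s) from the (delayed) spike center, in steps.
#' @param sigma kernel width in steps (> 0).
#' @param kernel_k tap count of the truncated window; `Inf` disables
#'   truncation.
#' @return kernel (or derivative) value(s), same shape as `u`.
#' @examples
#' gaussian_spike(0, 1)             # 1/sqrt(2*pi) ~ 0.3989
#' gaussian_delay_derivative(1, 1)  # exp(-0.5)/sqrt(2*pi) ~ 0.2420
#' @export
gaussian_spike <- function(u, sigma, kernel_k = Inf) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  ifelse(abs(u) <= kernel_k / 2,
         exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma), 0)
}

#' @rdname gaussian_spike
#' @export
gaussian_delay_derivative <- function(u, sigma, kernel_k = Inf) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  ifelse(abs(u) <= kernel_k / 2,
         u * exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma^3), 0)
}

#' Kernel tap table
#'
#' The kernel and its delay derivative sampled on the integer grid of the
#' truncated window — the software analogue of the look-up table a
#' hardware implementation would hold. The derivative taps are
#' antisymmetric with a zero center tap, so only `kernel_k` nonzero
#' entries are needed.
#'
#' @param sigma kernel width in steps.
#' @param kernel_k window tap count.
#' @return data.frame with columns `offset`, `value`, `derivative`.
#' @export
gaussian_kernel_table <- function(sigma = 2, kernel_k = 12L) {
  r <- floor(kernel_k / 2)
  u <- seq.int(-r, r)
  data.frame(offset = u,
             value = gaussian_spike(u, sigma, kernel_k),
             derivative = gaussian_delay_derivative(u, sigma, kernel_k))
}

#' Smoothed, delayed spike train and its delay-derivative trace
#'
#' Replaces each spike at time `t_k` by a truncated Gaussian centered at
#' `t_k + latency + shift(d)`, where `shift(d) = d + (D_max - 1)/2` maps
#' the continuous delay parameter onto the non-negative delay grid. The
#' derivative trace is the superposition of [gaussian_delay_derivative()]
#' at the same centers. Kernels are clipped at the raster boundaries
#' (simple truncation, no renormalization).
#'
#' By default the continuous shift is used, so the trace (and hence the
#' delay gradient) varies smoothly between integer delay settings; set
#' `rounded = TRUE` to center kernels at the integer effective delay
#' actually used by the binary forward pass.
#'
#' @param spike_times integer vector of spike step indices (1-based,
#'   within `[1, T]`).
#' @param d continuous delay parameter.
#' @param sim a [sim_params()] object (supplies `D_max`, `sigma`,
#'   `kernel_k`).
#' @param T sequence length in steps.
#' @param derivative if `TRUE`, return the delay-derivative trace instead
#'   of the smoothed train.
#' @param latency extra integer latency added to every center (1 for the
#'   mandatory one-step recurrence latency; 0 for inputs).
#' @param rounded center kernels at the rounded effective delay.
#' @return numeric vector of length `T`.
#' @examples
#' sim <- sim_params()
#' tr <- smoothed_delayed_train(2L, d = 5 - delay_half_range(sim), sim, T = 20L)
#' which.max(tr)  # 7: a spike at t = 2 delayed by 5 steps
#' @export
smoothed_delayed_train <- function(spike_times, d, sim, T,
                                   derivative = FALSE, latency = 0L,
                                   rounded = FALSE) {
  if (any(spike_times < 1L | spike_times > T))
    stop("`spike_times` must lie within [1, T]")
  shift <- if (rounded) effective_delay(d, sim$D_max)
           else clamp(d, -delay_half_range(sim), delay_half_range(sim)) +
                delay_half_range(sim)
  fn <- if (derivative) gaussian_delay_derivative else gaussian_spike
  half <- sim$kernel_k / 2
  out <- numeric(T)
  for (s in spike_times) {
    center <- s + latency + shift
    ts <- max(1L, ceiling(center - half)):min(T, floor(center + half))
    if (length(ts) == 0L || ts[1L] > ts[length(ts)]) next
    out[ts] <- out[ts] + fn(ts - center, sim$sigma, sim$kernel_k)
  }
  out
}

# Trace of the smoothed train (or its delay derivative) for a whole raster
# column given a continuous shift c >= 0; shared by the online rules and
# the oracle. latency = 1 for recurrent trains.
kernel_column_trace <- function(xcol, cshift, sim, deriv = FALSE,
                                latency = 0L) {
  Tn <- length(xcol)
  st <- which(xcol != 0)
  if (length(st) == 0L) return(numeric(Tn))
  fn <- if (deriv) gaussian_delay_derivative else gaussian_spike
  half <- sim$kernel_k / 2
  out <- numeric(Tn)
  for (s in st) {
    center <- s + latency + cshift
    lo <- max(1L, ceiling(center - half)); hi <- min(Tn, floor(center + half))
    if (lo > hi) next
    ts <- lo:hi
    out[ts] <- out[ts] + xcol[s] * fn(ts - center, sim$sigma, sim$kernel_k)
  }
  out
}
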
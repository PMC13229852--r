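#' On-chip memory cost model
#'
#' Bit-exact accounting of the memory needed to implement delayed
#' projections and their online learning on a neuromorphic device.
#'
#' A `memory_spec` collects layer sizes and bit widths: `B_w` bits per
#' weight, `B_d` bits per delay parameter (the delay buffer length is the
#' addressable range `2^B_d`, which must cover `D_max`), `B_v` bits per
#' membrane potential, and `k`, the tap count of the surrogate-kernel
#' look-up table.
#'
#' Three learning-support terms are modeled:
#' * `mem_axonal()`: `n_in * 2^B_d` bits — delaying each input spike train
#'   in a one-bit-per-timestep buffer both implements the axonal delay and
#'   preserves presynaptic spike timing for the updates.
#' * `mem_synaptic()`: `n_in * 2^B_d + n_hidden * 2^B_d * B_v` bits — the
#'   input-train buffer plus per-neuron ring buffers accumulating the
#'   delayed synaptic current at membrane resolution (the ring buffer
#'   loses presynaptic timing, so the input trains must still be kept).
#' * `mem_trace()`: `n_hidden * k * B_v` bits — buffering for the
#'   eligibility-trace / surrogate-kernel product.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param B_w weight resolution in bits.
#' @param B_d delay resolution in bits.
#' @param B_v membrane potential resolution in bits.
#' @param k surrogate look-up-table size (taps).
#' @return `memory_spec()` returns an object of class `memory_spec`; the
#'   `mem_*()` functions return bits.
#' @examples
#' ms <- memory_spec()
#' mem_axonal(ms)              # 3712 bits
#' mem_synaptic(ms)            # 69248 bits
#' mem_trace(ms)               # 24576 bits
#' @export
memory_spec <- function(n_in = 116L, n_hidden = 128L, n_out = 20L,
                        B_w = 8L, B_d = 5L, B_v = 16L, k = 12L) {
  v <- c(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
         B_w = B_w, B_d = B_d, B_v = B_v, k = k)
  if (any(v < 0) || any(v != round(v)))
    stop("all memory_spec fields must be non-negative integers")
  structure(as.list(v), class = "memory_spec")
}

#' @rdname memory_spec
#' @param spec a `memory_spec`.
#' @export
mem_axonal <- function(spec) spec$n_in * 2^spec$B_d

#' @rdname memory_spec
#' @export
mem_synaptic <- function(spec)
  spec$n_in * 2^spec$B_d + spec$n_hidden * 2^spec$B_d * spec$B_v

#' @rdname memory_spec
#' @export
mem_trace <- function(spec) spec$n_hidden * spec$k * spec$B_v

#' Parameter count of an architecture
#'
#' Counts weights (input, readout and, for recurrent nets, recurrent;
#' scaled by mask density when sparse) plus delay parameters by flavor:
#' none, one per presynaptic neuron (axonal), or one per connection
#' (synaptic).
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param flavor_in,flavor_rec delay flavor per projection.
#' @param recurrent include a recurrent projection.
#' @param density_in,density_rec connection density (1 = dense).
#' @return number of parameters.
#' @examples
#' param_count(116, 128, 20)                            # 17408
#' param_count(116, 128, 20, flavor_in = "synaptic")    # 32256
#' param_count(116, 128, 20, flavor_in = "axonal")      # 17524
#' @export
param_count <- function(n_in, n_hidden, n_out,
                        flavor_in = c("none", "axonal", "synaptic"),
                        flavor_rec = c("none", "axonal", "synaptic"),
                        recurrent = FALSE,
                        density_in = 1, density_rec = 1) {
  flavor_in <- match.arg(flavor_in); flavor_rec <- match.arg(flavor_rec)
  n_syn_in <- round(n_in * n_hidden * density_in)
  total <- n_syn_in + n_hidden * n_out
  total <- total + switch(flavor_in, none = 0, axonal = n_in,
                          synaptic = n_syn_in)
  if (recurrent) {
    n_syn_rec <- round(n_hidden * n_hidden * density_rec)
    total <- total + n_syn_rec +
      switch(flavor_rec, none = 0, axonal = n_hidden, synaptic = n_syn_rec)
  }
  total
}

#' Total memory footprint of a feedforward configuration
#'
#' Breaks the on-chip memory of a single-hidden-layer feedforward network
#' into parameter storage (weights at `B_w` bits, delay parameters at
#' `B_d` bits per their flavor and cardinality, input weights scaled by
#' `density`), membrane state (`(n_hidden + n_out) * B_v` bits), and the
#' learning-support terms for the chosen delay flavor. Also reports the
#' minimum input-layer sparsity at which the flavored model fits within
#' the memory budget of the dense weights-only baseline.
#'
#' @param spec a [memory_spec()].
#' @param flavor `"weights_only"`, `"axonal"` or `"synaptic"`.
#' @param density input connection density (1 = dense).
#' @return list with components `parameters`, `state`, `learning`,
#'   `total` (bits) and, for delay flavors, `min_sparsity_to_fit`.
#' @examples
#' memory_footprint(memory_spec(), "weights_only")$total  # 141632 bits
#' @export
memory_footprint <- function(spec, flavor = c("weights_only", "axonal",
                                              "synaptic"),
                             density = 1) {
  flavor <- match.arg(flavor)
  n_syn <- round(spec$n_in * spec$n_hidden * density)
  w_bits <- (n_syn + spec$n_hidden * spec$n_out) * spec$B_w
  d_bits <- switch(flavor, weights_only = 0,
                   axonal = spec$n_in * spec$B_d,
                   synaptic = n_syn * spec$B_d)
  state_bits <- (spec$n_hidden + spec$n_out) * spec$B_v
  learn_bits <- switch(flavor, weights_only = 0,
                       axonal = mem_axonal(spec) + mem_trace(spec),
                       synaptic = mem_synaptic(spec) + mem_trace(spec))
  out <- list(parameters = w_bits + d_bits, state = state_bits,
              learning = learn_bits,
              total = w_bits + d_bits + state_bits + learn_bits)
  if (flavor != "weights_only") {
    budget <- memory_footprint(spec, "weights_only")$total
    # bits that do not scale with input density
    fixed <- spec$n_hidden * spec$n_out * spec$B_w + state_bits + learn_bits +
      if (flavor == "axonal") spec$n_in * spec$B_d else 0
    per_syn <- spec$B_w + if (flavor == "synaptic") spec$B_d else 0
    dense_syn_bits <- spec$n_in * spec$n_hidden * per_syn
    max_density <- (budget - fixed) / dense_syn_bits
    out$min_sparsity_to_fit <- 1 - clamp(max_density, 0, 1)
  }
  out
}

#' Sparsity sweep of the memory model
#'
#' Evaluates [memory_footprint()] over a grid of input densities for one
#' delay flavor, for exploring how much structural sparsity buys back the
#' delay-learning overhead.
#'
#' @param spec a [memory_spec()].
#' @param flavor delay flavor (see [memory_footprint()]).
#' @param densities vector of input densities to evaluate.
#' @return data.frame with one row per density.
#' @export
memory_sweep <- function(spec, flavor = "synaptic",
                         densities = seq(0.1, 1, by = 0.1)) {
  rows <- lapply(densities, function(d) {
    fp <- memory_footprint(spec, flavor, density = d)
    data.frame(density = d, sparsity = 1 - d, parameters = fp$parameters,
               state = fp$state, learning = fp$learning, total = fp$total)
  })
  out <- do.call(rbind, rows)
  out$fits_weights_only_budget <-
    out$total <= memory_footprint(spec, "weights_only")$total
  out
}

#' Memory report for a configuration
#'
#' Convenience table of the bit cost per component for all three flavors.
#'
#' @param spec a [memory_spec()].
#' @return data.frame with one row per flavor.
#' @export
memory_report <- function(spec = memory_spec()) {
  rows <- lapply(c("weights_only", "axonal", "synaptic"), function(fl) {
    fp <- memory_footprint(spec, fl)
    data.frame(flavor = fl, parameters = fp$parameters, state = fp$state,
               learning = fp$learning, total = fp$total,
               min_sparsity_to_fit = fp$min_sparsity_to_fit %||% NA_real_)
  })
  do.call(rbind, rows)
}
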
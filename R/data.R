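# Synthetic spike-raster generators that make delay learning testable
# without any external data, plus an optional reader for the SHD/SSC
# HDF5 distribution.

#' Fixed random binary sparsity mask
#'
#' Bernoulli(density) mask, drawn once and held fixed for a run.
#'
#' @param shape integer vector `c(n_rows, n_cols)`.
#' @param density probability that an entry is connected, in (0, 1].
#' @param seed optional seed; the caller's RNG state is restored.
#' @return binary matrix of the requested shape.
#' @export
make_sparsity_mask <- function(shape, density, seed = NULL) {
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  matrix(stats::rbinom(prod(shape), 1L, density), shape[1L], shape[2L])
}

#' Specification of the planted-latency synthetic task
#'
#' Classes share identical per-channel spike counts and differ only in
#' planted relative latencies: on every input "volley", channel `i` of a
#' class-`c` sample fires `planted_latencies[c, i]` steps *before* the
#' volley reference time, so a postsynaptic delay equal to the planted
#' latency re-aligns the arrivals. Rate-based discrimination is
#' impoverished by construction; delay alignment solves the task.
#'
#' Volley reference times are drawn per sample with irregular spacing
#' (minimum gap `min_gap`), which removes absolute-time cues and breaks
#' the modulo-spacing ambiguity of periodic volleys.
#'
#' @param n_in input channels.
#' @param n_classes number of classes.
#' @param T sequence length in steps.
#' @param dt milliseconds per step.
#' @param max_offset largest planted latency in steps.
#' @param spikes_per_channel volleys (and hence spikes per channel) per
#'   sample.
#' @param jitter_sd per-spike timing noise (steps, Gaussian, rounded).
#' @param planted_latencies optional `n_classes x n_in` integer matrix;
#'   by default channel 1 is the zero-latency reference and the remaining
#'   entries are drawn uniformly from `0:max_offset` (distinct rows).
#' @param min_gap minimum spacing between volley reference times.
#' @param tail_margin steps reserved at the end of the raster so delayed
#'   arrivals (delays up to the midpoint of the grid) stay inside it.
#' @param seed RNG seed for the planted latencies.
#' @return an object of class `latency_task_spec`.
#' @export
latency_task_spec <- function(n_in = 4L, n_classes = 2L, T = 50L, dt = 10,
                              max_offset = 6L, spikes_per_channel = 4L,
                              jitter_sd = 0, planted_latencies = NULL,
                              min_gap = 8L, tail_margin = 14L, seed = 1L) {
  if (is.null(planted_latencies)) {
    set.seed(seed)
    for (try in 1:20000) {
      planted_latencies <- cbind(
        0L, matrix(sample.int(max_offset + 1L,
                              n_classes * (n_in - 1L), replace = TRUE) - 1L,
                   n_classes, n_in - 1L))
      if (nrow(unique(planted_latencies)) == n_classes &&
          latencies_separated(planted_latencies)) break
      if (try == 20000L)
        stop("could not draw separable class latencies; increase ",
             "`max_offset` or reduce `n_classes`")
    }
  }
  planted_latencies <- as.matrix(planted_latencies)
  if (any(planted_latencies >= T)) stop("planted latencies must be < T")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  structure(list(n_in = n_in, n_classes = n_classes, T = as.integer(T),
                 dt = dt, max_offset = max_offset,
                 spikes_per_channel = as.integer(spikes_per_channel),
                 jitter_sd = jitter_sd,
                 planted_latencies = planted_latencies,
                 min_gap = as.integer(min_gap),
                 tail_margin = as.integer(tail_margin), seed = seed),
            class = "latency_task_spec")
}

# Class patterns must be separable by coincidence detection: with delays
# tuned to one class, the other classes' arrivals must not form a
# 3-cluster within +/-1 step, and no more than about half the channels
# may sit near alignment (within one step; within three for the
# two-channel task, whose detector tolerates a one-step misalignment).
# Either failure would let a coincidence detector fire on the wrong
# class.
latencies_separated <- function(L) {
  K <- nrow(L); n_in <- ncol(L)
  if (K < 2L) return(TRUE)
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    d <- L[a, ] - L[b, ]
    cl <- max(vapply(d, function(x) sum(abs(d - x) <= 1), integer(1L)))
    if (cl > 2L) return(FALSE)
    if (n_in == 2L && abs(d[2L]) <= 3) return(FALSE)
  }
  TRUE
}

#' Generate a labeled planted-latency dataset
#'
#' Deterministic given `(spec, seed)`. Every sample has exactly
#' `spikes_per_channel` spikes per channel (up to boundary clipping and
#' jitter collisions), so per-class mean spike counts are equal by
#' construction.
#'
#' @param spec a [latency_task_spec()].
#' @param n_samples number of rasters to generate.
#' @param seed RNG seed for sampling (defaults to `spec$seed`).
#' @return an object of class `spike_dataset`: list with `rasters` (list
#'   of [spike_raster()]), integer `labels`, and the `spec`.
#' @export
make_latency_dataset <- function(spec, n_samples, seed = spec$seed) {
  set.seed(seed)
  labels <- rep_len(seq_len(spec$n_classes), n_samples)
  labels <- labels[sample.int(n_samples)]
  # volley reference times live away from both raster edges so planted
  # offsets (early side) and network delays up to the midpoint of the
  # delay grid (late side) stay inside the raster
  w_lo <- spec$max_offset + 1L
  w_hi <- spec$T - spec$tail_margin
  n_v <- spec$spikes_per_channel
  rasters <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    avail <- (w_hi - w_lo) - (n_v - 1L) * spec$min_gap
    if (avail < 0) stop("T too short for the requested volley count/gap")
    base <- w_lo + sort(stats::runif(n_v, 0, avail)) +
      (seq_len(n_v) - 1L) * spec$min_gap
    base <- round_half_up(base)
    m <- matrix(0, spec$T, spec$n_in)
    lat <- spec$planted_latencies[labels[s], ]
    for (i in seq_len(spec$n_in)) {
      tt <- base - lat[i]
      if (spec$jitter_sd > 0)
        tt <- tt + round_half_up(stats::rnorm(n_v, 0, spec$jitter_sd))
      tt <- tt[tt >= 1 & tt <= spec$T]
      m[tt, i] <- 1
    }
    rasters[[s]] <- spike_raster(m, dt = spec$dt, label = labels[s])
  }
  structure(list(rasters = rasters, labels = labels, spec = spec),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("spike_dataset: %d samples, %d classes, %d x %d rasters\n",
              length(x$rasters), length(unique(x$labels)),
              n_steps(x$rasters[[1L]]), n_channels(x$rasters[[1L]])))
  invisible(x)
}

#' Two-channel coincidence-detection fixture
#'
#' Two input channels spike `offset` steps apart; an output neuron
#' receives both through weights that are each subthreshold but
#' super-threshold when summed. Without delays the postsynaptic
#' potentials arrive apart and no spike is produced; delaying the earlier
#' channel by `offset` makes the arrivals coincident and the neuron
#' fires.
#'
#' @param offset firing offset between the two channels, in steps.
#' @param sim a [sim_params()] object (`offset` must be < `D_max`).
#' @param T raster length in steps.
#' @param t0 spike time of the earlier channel.
#' @param w synaptic weight per channel, as a fraction of `v_th`
#'   (0.5 < w < 1 for the coincidence regime).
#' @return list with the `raster`, `net_no_delay` (both delays at the
#'   no-delay bound) and `net_compensating` (earlier channel delayed by
#'   `offset`).
#' @export
make_coincidence_pair <- function(offset = 3L, sim = sim_params(),
                                  T = 20L, t0 = 3L, w = 0.6) {
  if (offset >= sim$D_max) stop("`offset` must be < D_max")
  if (w <= 0.5 || w >= 1) stop("`w` must be in (0.5, 1) for coincidence")
  m <- matrix(0, T, 2L)
  m[t0, 1L] <- 1; m[t0 + offset, 2L] <- 1
  R <- delay_half_range(sim)
  W_in <- matrix(w * sim$v_th, 1L, 2L)
  W_out <- matrix(0, 1L, 1L)
  D0 <- matrix(-R, 1L, 2L)
  Dc <- D0; Dc[1L, 1L] <- offset - R
  list(raster = spike_raster(m, dt = sim$dt),
       net_no_delay = network_params(W_in, W_out, D_in = D0,
                                     flavor_in = "synaptic"),
       net_compensating = network_params(W_in, W_out, D_in = Dc,
                                         flavor_in = "synaptic"))
}

#' Hand-constructed coincidence-detector network for the latency task
#'
#' One hidden neuron per class with uniform subthreshold weights; with
#' the planted delays the class neuron's inputs arrive coincidentally and
#' it fires on every volley of its own class. The readout weights are
#' fixed +1 for the neuron's class and `-1/(n_classes-1)` elsewhere.
#'
#' @param spec a [latency_task_spec()].
#' @param sim a [sim_params()] object.
#' @param planted if `TRUE`, set the delays to the planted latencies
#'   (`effective_delay` equal to the latency); if `FALSE`, start all
#'   delays at the midpoint of the range (no relative delay).
#' @param w_sum summed input weight per hidden neuron, as a multiple of
#'   `v_th` (> 1 so full coincidence fires, each individual arrival
#'   subthreshold).
#' @return a [network_params()] object.
#' @export
latency_probe_network <- function(spec, sim = sim_params(), planted = FALSE,
                                  w_sum = 1.25) {
  K <- spec$n_classes
  n_in <- spec$n_in
  W_in <- matrix(w_sum * sim$v_th / n_in, K, n_in)
  W_out <- matrix(-1 / max(K - 1, 1), K, K)
  diag(W_out) <- 1
  R <- delay_half_range(sim)
  D_in <- if (planted) spec$planted_latencies - R
          else matrix(0, K, n_in)
  network_params(W_in, W_out, D_in = D_in, flavor_in = "synaptic")
}

# --- SHD / SSC -------------------------------------------------------------

#' Bin an event stream into a binary spike raster
#'
#' Spatial binning groups `bin_channels` adjacent units into one channel
#' (OR-reduction keeps the raster binary; `floor(n_units/bin_channels)`
#' channels, remainder units dropped) and temporal binning uses half-open
#' `[t, t + bin_time_ms)` windows.
#'
#' @param times_ms event times in milliseconds (0-based).
#' @param units 0-based unit ids.
#' @param n_units total units in the source stream (700 for SHD/SSC).
#' @param bin_channels spatial binning factor (default 6: 700 -> 116).
#' @param bin_time_ms temporal bin in milliseconds (default 10).
#' @param T_steps raster length; defaults to spanning the last event.
#' @return a [spike_raster()].
#' @export
bin_events <- function(times_ms, units, n_units = 700L, bin_channels = 6L,
                       bin_time_ms = 10, T_steps = NULL) {
  n_ch <- n_units %/% bin_channels
  if (is.null(T_steps))
    T_steps <- max(1L, floor(max(times_ms, 0) / bin_time_ms) + 1L)
  m <- matrix(0, T_steps, n_ch)
  if (length(times_ms)) {
    ch <- units %/% bin_channels + 1L
    tb <- floor(times_ms / bin_time_ms) + 1L
    keep <- ch >= 1L & ch <= n_ch & tb >= 1L & tb <= T_steps
    m[cbind(tb[keep], ch[keep])] <- 1
  }
  spike_raster(m, dt = bin_time_ms)
}

#' Read an SHD/SSC HDF5 file with the standard preprocessing
#'
#' Reads the published HDF5 layout (`spikes/times` in seconds,
#' `spikes/units`, `labels`) by delegating the HDF5 decoding to the
#' `h5py` Python library (a `python` executable with `h5py` must be on
#' the PATH), then bins each sample with [bin_events()]. Entirely
#' optional: nothing else in the package requires it.
#'
#' @param path path to e.g. `shd_test.h5`.
#' @param bin_channels spatial binning factor (default 6).
#' @param bin_time_ms temporal bin (default 10 ms).
#' @param T_steps fixed raster length (default 100 steps, i.e. 1 s).
#' @param max_samples optionally truncate the dataset.
#' @param python python executable to use.
#' @return a `spike_dataset` (labels converted to 1-based).
#' @export
load_shd <- function(path, bin_channels = 6L, bin_time_ms = 10,
                     T_steps = 100L, max_samples = Inf,
                     python = Sys.which("python")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!nzchar(python)) stop("no `python` executable found for HDF5 decoding")
  tmp <- tempfile(fileext = ".tsv")
  code <- paste(
    "import sys, h5py",
    "f = h5py.File(sys.argv[1], 'r')",
    "times = f['spikes/times']; units = f['spikes/units']",
    "labels = f['labels'][:]",
    "out = open(sys.argv[2], 'w')",
    "for i in range(len(labels)):",
    "    t = times[i]; u = units[i]",
    "    for j in range(len(t)):",
    "        out.write('%d\\t%.6f\\t%d\\n' % (i, t[j], u[j]))",
    "    out.write('%d\\t-1\\t%d\\n' % (i, labels[i]))",
    "out.close()",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(code), shQuote(path),
                              shQuote(tmp)))
  if (status != 0) stop("h5py decoding failed (status ", status, ")")
  ev <- utils::read.table(tmp, sep = "\t",
                          col.names = c("sample", "time", "unit"))
  unlink(tmp)
  lab_rows <- ev$time < 0
  labels <- ev$unit[lab_rows] + 1L
  ids <- ev$sample[lab_rows]
  n <- min(length(labels), max_samples)
  rasters <- vector("list", n)
  for (s in seq_len(n)) {
    sel <- ev$sample == ids[s] & !lab_rows
    rasters[[s]] <- bin_events(ev$time[sel] * 1000, ev$unit[sel],
                               bin_channels = bin_channels,
                               bin_time_ms = bin_time_ms,
                               T_steps = T_steps)
    rasters[[s]]$label <- labels[s]
  }
  structure(list(rasters = rasters, labels = labels[seq_len(n)],
                 spec = list(source = path, bin_channels = bin_channels,
                             bin_time_ms = bin_time_ms, T_steps = T_steps)),
            class = "spike_dataset")
}
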
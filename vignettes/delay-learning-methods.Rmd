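---
title: "Online three-factor learning of weights and delays in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online three-factor learning of weights and delays in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayprop)
```

## The model

`delayprop` simulates single-hidden-layer spiking networks of leaky
integrate-and-fire (LIF) neurons in discrete time. Neuron $j$ integrates
delayed, weighted presynaptic spikes with a geometric leak and a soft
reset by threshold subtraction:

$$v_j^{t+1} = \alpha\, v_j^t + \sum_i W^{in}_{ji}\, x_i^{t - D^{in}_{ji}}
  \;+\; \sum_i W^{rec}_{ji}\, z_i^{t - D^{rec}_{ji} - 1}
  \;-\; z_j^t\, v_{th}, \qquad z_j^{t+1} = H(v_j^{t+1} > v_{th}),$$

where $\alpha = e^{-\Delta t/\tau_m}$, the recurrent term (optional)
carries one mandatory step of latency on top of its learned delay, and
the threshold comparison is strict. A non-spiking leaky-integrator
readout $y^t = \kappa\, y^{t-1} + W^{out} z^t$ feeds a per-step softmax;
for a one-hot target the loss is
$E = -\sum_t \log \hat\pi^t_{k^*}$ and the prediction is the argmax of
the time-summed softmax outputs. The readout carries no delays.

Delays come in two flavors per projection: *synaptic* (one parameter per
connection) and *axonal* (one parameter per presynaptic neuron, shared
by all of its outgoing connections). A continuous delay parameter $d$
lives in $[-(D_{max}-1)/2,\, +(D_{max}-1)/2]$; the forward pass uses
only the rounded, clipped integer `effective_delay(d, D_max)` in
$[0, D_{max}-1]$, with the lower bound meaning "no delay". The forward
pass is strictly binary — no smoothing ever enters simulation.

## The learning rules

All parameters are updated online by three-factor rules: per-parameter
eligibility traces built from local quantities, gated by a top-down
learning signal $L_j^t = \sum_k W^{out}_{kj} (\hat\pi_k^t - \pi^*_k)$
from the readout error. For a weight the eligibility is the
$\alpha$-filtered delayed presynaptic activity times the
piecewise-linear spike surrogate
$\psi(v) = (\gamma_{pd}/v_{th}) \max(0, 1 - |v - v_{th}|/v_{th})$.

Delays require a derivative of a spike train with respect to its own
time shift, which does not exist for binary spikes. Inside learning
computations only, each spike is therefore replaced by a symmetric
Gaussian kernel of width $\sigma$ truncated to a window of
`kernel_k` taps; its derivative with respect to the delay parameter is
available in closed form and is positive for times after the delayed
spike center (a larger delay moves the smoothed spike later). The delay
eligibility filters the weighted kernel-derivative drive
$W_{ji}\, \mathrm{d}\hat x_i(t - D_{ji})/\mathrm{d}D_{ji}$ through the
same $\alpha$ recursion and the same surrogate gate. Axonal delays
accumulate the contributions of all postsynaptic neurons into their one
shared parameter.

The exact learning signal contains an acausal sum over future readout
errors weighted by $\kappa^{t'-t}$. The package implements it two ways:

* **online** (the operating mode): the instantaneous signal is used and
  the $\kappa$ filter is absorbed into $\kappa$-filtered eligibility
  traces — an exact rearrangement of the same total gradient that needs
  only causally available quantities;
* **offline-exact** (for verification): the future sum is evaluated
  literally after the sequence.

Both are verified to agree to machine precision, and both equal the
locality-matched unrolled reference gradient (below) on feedforward
networks. Updates are plain SGD on batch-mean gradients (batch 16 by
default), with continuous delays clamped to their legal range after
every update and masked connections left untouched. The reset term is
treated as constant in all gradient paths, and recurrent-spike credit
is not propagated — the standard locality approximation of online
eligibility-based learning; on recurrent networks the package reports,
but does not hide, the gap to the full gradient.

## The gradient oracle

`unrolled_gradient()` provides two brute-force references:

* **locality_matched** — reverse-mode differentiation over the true
  binary forward pass with the same local substitutions as the online
  rules (surrogate at thresholds, Gaussian derivative on delay paths,
  reset and recurrent-spike credit detached). On feedforward networks
  this must equal the online gradients up to floating-point summation
  order; the test suite checks agreement to a relative 1e-9 over
  batches of random configurations.
* **full** — the exact gradient of a fully smooth relaxation in which
  delayed trains are Gaussian-smoothed and the threshold is replaced by
  a $C^1$ spike function whose derivative is exactly the
  piecewise-linear surrogate. With binary thresholds the loss is
  piecewise constant in the delay parameters, so a finite-difference
  check is only meaningful on such a relaxation; central differences on
  it validate every term of the delay pathway independently of the
  online implementation.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.6 | membrane decay per step, $e^{-\Delta t/\tau_m}$ |
| `kappa` | $e^{-0.01} \approx 0.990$ | readout decay; $\tau_o = 1$ s at $\Delta t = 10$ ms |
| `v_th` | 1.0 | firing threshold (unit normalization; dynamics are invariant to joint rescaling with the weights) |
| `dt` | 10 ms | timestep |
| `D_max` | 25 | delay grid; 250 ms maximum latency at 10 ms steps |
| `gamma_pd` | 0.3 | surrogate dampening |
| `sigma` | 2 steps | Gaussian kernel width |
| `kernel_k` | 12 taps | truncated kernel window (and the size of the hardware look-up table in the memory model) |
| `lr_w`, `lr_d` | 1e-4, 1e-2 | weight and delay learning rates |
| `batch_size` | 16 | sequences per update |

The kernel width and window are deliberately modest: symmetry matters
for stable delay learning far more than the precise width, and a 12-tap
window keeps the trace-buffering cost (`mem_trace`) small. Truncation is
plain windowing without renormalization, and kernels are clipped at the
raster boundaries. Delay derivatives are evaluated at the continuous
delay value rather than the rounded one, so gradients vary smoothly
between integer settings (`smoothed_delayed_train(rounded = TRUE)`
exposes the alternative). Weight initialization is zero-mean uniform at
$1/\sqrt{\text{fan-in}}$ scale, delays uniform over the legal range,
everything seeded; there are no bias terms anywhere.

## Synthetic tasks

The package generates its own delay-sensitive data:

* `make_coincidence_pair()` reproduces the canonical two-input
  coincidence motif: two channels spiking a fixed offset apart, weights
  each subthreshold but super-threshold in sum. Without delays the
  postsynaptic potentials arrive apart and the neuron is silent; a
  compensating delay on the earlier channel makes it fire.
* `make_latency_dataset()` builds a classification task in which
  classes share identical per-channel spike counts and differ only in
  planted per-channel latencies relative to randomly timed input
  volleys, so rate information is uninformative by construction and
  delay alignment solves the task. Volley times are drawn per sample
  with irregular spacing: periodic volleys would make delay solutions
  ambiguous modulo the period, and fixed volley times would leak
  absolute-time cues. Generated class patterns are rejected unless a
  coincidence detector tuned to one class stays subthreshold on every
  other class (no wrong-class 3-cluster within one step; at most half
  the channels within three steps).

What the generator emulates: precisely timed, volley-structured spike
patterns whose class identity lives purely in relative timing — the
regime in which learnable delays matter. What it does not emulate:
the channel correlations, rate gradients, and variable sequence
lengths of cochlear-model speech data (SHD/SSC). Passing the synthetic
tests therefore demonstrates that the rules learn *timing* structure
online, not that they reach any particular accuracy on real speech
benchmarks; `load_shd()` is provided for running the real thing when
the HDF5 files are available.

## The delay-recovery experiment

`delay_recovery_run()` freezes the weights of a hand-constructed
coincidence probe (one detector per class, fixed readout) and lets only
the input delays learn. Three choices deserve explanation:

* **Relative scoring.** Coincidence constrains delays only up to a
  common per-neuron shift, so recovery is scored on relative offsets
  (each channel's delay minus channel 1's), comparing the integer
  delays the binary forward pass actually uses against the planted
  latencies.
* **Two channels by default.** With more channels the loss surface
  acquires local minima in which a *partial* subset of channels forms a
  coincidence that already classifies correctly, stalling refinement —
  an optimization artifact of the probe task, not of the rule (starting
  at the planted solution, training stays there; diagnosed during
  design on 4-channel variants). Two channels make the per-neuron
  landscape one-dimensional and the planted alignment its only
  attractor.
* **A one-step tolerance band.** The converged delays sit within about
  one step of the planted offsets rather than exactly on them: the
  eligibility filter smears the antisymmetric kernel derivative
  causally in time, displacing the fixed point slightly — an intrinsic,
  reproducible property of the online rule at these constants. The
  probe weights (`w_sum = 1.36`) are therefore set so the detector
  fires when its inputs arrive within one step and stays silent beyond,
  which makes the classification readout robust to that bias while the
  class-separation constraint (planted patterns at least 4 steps apart)
  keeps wrong-class firing impossible.

The packaged acceptance suite runs this experiment over five seeds and
requires integer recovery within one step plus perfect test accuracy in
at least four of them, alongside a directional control on a 16-neuron
co-learning network: learnable delays must beat fixed random delays on
mean accuracy over shared seeds. Full-scale speech benchmarks are out
of desk scale (external downloads, tens of epochs on 10k samples);
ready-made configurations are shipped instead (see the README) and the
synthetic results are the supported evidence.

## The memory model

For deployment accounting, `memory_spec()` + `memory_footprint()`
implement a bit-exact cost model: weights at `B_w` bits, delays at
`B_d` bits, membrane state at `B_v` bits. Delay learning adds buffering:

* axonal: `n_in * 2^B_d` bits (the delayed input train itself, one bit
  per buffered timestep — the buffer both implements the delay and
  preserves presynaptic timing for the updates);
* synaptic: additionally `n_hidden * 2^B_d * B_v` bits of
  delayed-current ring buffers at membrane resolution;
* both: `n_hidden * k * B_v` bits for the eligibility/kernel product
  (the `k`-tap look-up table of the kernel derivative).

`2^B_d` is the buffer length implied by a `B_d`-bit delay address; the
reading "2·B_d" is arithmetically inconsistent with the reference
totals this model reproduces (141.632k, 28.288k and 93.824k bits at the
116-128-20 configuration with 8/5/16-bit quantization and k = 12), as
noted in the source. The minimum-sparsity calculation counts membrane
state, readout weights and delay parameters inside the fixed budget;
published rounded thresholds for the same quantities (20% and 78%)
follow a different, unstated accounting and are reported alongside
rather than asserted.

## Numerical choices and degenerate inputs

* Delay rounding is half-up, so the integer grid is deterministic
  across platforms; clamping absorbs out-of-range parameters silently.
* Strict threshold comparison (`v > v_th`) means a membrane exactly at
  threshold does not spike.
* The softmax is computed with max-subtraction; normalization is exact
  to 1e-12 per step.
* Empty spike trains yield zero traces and zero gradients; masked
  connections contribute nothing to dynamics, eligibilities or
  updates, and recurrent self-connections are forced to zero.
* The unrolled oracle refuses sequences longer than a guard (default
  2000 steps) rather than exhausting memory.
* Sequence sweeps cache the per-sequence input currents and kernel
  traces as whole-raster arrays for vectorization; the recursions
  themselves only ever touch state within the delay buffer and kernel
  window, which is what a streaming implementation would keep.

## Problem sizes

The shipped tests and experiments run at deliberately small scale:
gradient checks on networks up to 8 inputs x 6 hidden x 50 steps,
recovery and control experiments with 2-6 input channels, at most 16
hidden neurons, sequences of 64 steps and a few thousand training
sequences per run. These sizes were chosen so the whole evidence chain
(exact oracle equality, finite-difference validation, delay recovery,
learnable-vs-fixed control) is reproducible in minutes on one CPU;
the same code paths scale to the 116-input speech configurations via
`run_config()`.

## Known limitations

* One hidden layer only; the locality approximation is known to lose
  accuracy with depth, and the package does not pretend otherwise.
* No optimizer beyond plain SGD, no schedules, no regularizers.
* The axonal-delay gradient shares one parameter across all
  postsynaptic neurons; accumulated approximation error makes it the
  weaker of the two flavors, consistent with its control experiments.
* The on-chip memory model counts bits; it does not implement
  fixed-point arithmetic.
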
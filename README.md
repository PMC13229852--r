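# delayprop

Online learning of synaptic weights **and transmission delays** in
spiking neural networks.

Most trainable spiking networks adjust only synaptic weights, which
carry little information about *when* spikes should interact. A
per-connection (synaptic) or per-neuron (axonal) delay shifts the
moment a presynaptic spike influences the postsynaptic membrane: tuned
delays make unrelated inputs arrive coincidentally (driving a neuron
above threshold) or spread unwanted coincidences apart. `delayprop` is
for computational neuroscientists and neuromorphic-hardware designers
who want delays to be *learned online* — during a single forward sweep,
with memory independent of sequence length — rather than by
backpropagation through time.

## What the package implements

**Dynamics.** Discrete-time leaky integrate-and-fire (LIF) hidden
layers with optional recurrence and integer transmission delays up to
`D_max` steps,

```
v[t+1] = alpha * v[t] + sum_i W_in[j,i]  * x[i, t - D_in[j,i]]
                      + sum_i W_rec[j,i] * z[i, t - D_rec[j,i] - 1]
                      - z[j,t] * v_th,       z[t+1] = H(v[t+1] > v_th),
```

a non-spiking leaky-integrator readout `y[t] = kappa*y[t-1] + W_out z[t]`,
per-step softmax, and cross-entropy loss summed over time. The forward
pass is strictly binary.

**Learning.** Three-factor rules: per-parameter eligibility traces
(filtered local pre/post co-activity) gated by a top-down learning
signal from the readout error. Delay gradients exist because — inside
learning computations only — each spike is smoothed by a symmetric
truncated Gaussian kernel whose derivative with respect to the delay is
closed-form. Weights, synaptic delays and axonal delays (input and
recurrent) are co-learned or frozen independently; updates are plain
SGD over mini-batches with delay clamping.

**Verification.** A brute-force unrolled gradient oracle:
`locality_matched` mode must equal the online rules to a relative
1e-9 on feedforward networks, and `full` mode (exact gradient of a
smooth relaxation) is validated against central finite differences.

**Memory model.** A bit-exact cost model of on-chip deployment:
parameter storage, membrane state, and the buffering that delay
*learning* adds (`mem_axonal`, `mem_synaptic`, `mem_trace`), plus the
minimum sparsity at which a delay-learning model fits a weights-only
budget.

**Data.** Seeded synthetic generators that make delay learning testable
offline — a coincidence-detection motif and a planted-latency
classification task whose classes differ only in relative spike timing
— plus an optional reader for the SHD/SSC spiking speech datasets
(700 channels binned to 116, 10 ms bins).

## Worked example

Two input channels fire 3 steps apart; the weights are each
subthreshold but super-threshold in sum, so only coincident arrivals
can drive a spike:

```r
library(delayprop)
sim <- sim_params()          # alpha = 0.6, v_th = 1, D_max = 25 (250 ms)
cp <- make_coincidence_pair(offset = 3L, sim = sim)
sum(forward_pass(cp$raster, cp$net_no_delay,     sim)$z)   # 0
sum(forward_pass(cp$raster, cp$net_compensating, sim)$z)   # 1
```

With no delays the postsynaptic potentials arrive apart and the output
neuron is silent (`0` spikes); delaying the earlier channel by the
3-step offset makes them coincide and the neuron fires (`1` spike).

Delays are *recovered* from data by the online rules: the
planted-latency task hides class identity purely in relative spike
timing, and training only the delays of a frozen-weight coincidence
probe finds the planted offsets:

```r
r <- delay_recovery_run(seed = 1)
r$planted          #      [,1] [,2]
                   # [1,]    0    0
                   # [2,]    0    4
r$learned_int      #      [,1] [,2]
                   # [1,]    0   -1
                   # [2,]    0    3
r$max_offset_error # 1
r$test_acc         # 1
```

The learned integer offsets land within one step of the planted ones
(the residual one-step bias is an intrinsic property of the causal
eligibility filtering, discussed in the methods vignette) and test
accuracy is perfect. The memory model reproduces the deployment
arithmetic for a 116-128-20 network at 8-bit weights, 5-bit delays and
16-bit membranes:

```r
spec <- memory_spec()
memory_footprint(spec, "weights_only")$total   # 141632 bits
mem_axonal(spec) + mem_trace(spec)             # 28288 bits
mem_synaptic(spec) + mem_trace(spec)           # 93824 bits
```

## Command line

```sh
inst/cli/delayprop memory --n_in 116 --n_hidden 128 --n_out 20
inst/cli/delayprop gradcheck --seed 1
inst/cli/delayprop synth --out rasters/ --n 64
inst/cli/delayprop train --config cfg.yaml --out results/
```
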
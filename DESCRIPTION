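Package: delayprop
Title: Online Learning of Synaptic Weights and Delays in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time simulation of leaky integrate-and-fire (LIF)
    spiking networks with per-synapse or per-neuron (axonal) transmission
    delays, and online three-factor learning rules that adjust weights and
    delays jointly from eligibility traces gated by a top-down learning
    signal. Delay gradients are obtained by smoothing spike trains with a
    symmetric Gaussian kernel whose delay derivative is available in closed
    form; the smoothing is used only inside learning computations while the
    forward pass stays strictly binary. Includes a brute-force unrolled
    gradient oracle for verification, an on-chip memory cost model for
    neuromorphic deployments, and synthetic temporal-pattern tasks
    (coincidence detection, planted latencies) that exercise delay learning
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
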
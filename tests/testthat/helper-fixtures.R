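# Shared fixtures: small random networks and rasters, built in code.

random_raster <- function(Tn, n_in, p = 0.2) {
  matrix(stats::rbinom(Tn * n_in, 1L, p), Tn, n_in)
}

# Small feedforward net with enough drive to spike occasionally.
random_ff_net <- function(n_in, n_hidden, n_out, sim,
                          flavor = "synaptic", seed = 1L, density = 1,
                          w_scale = 6) {
  net <- init_network(n_in, n_hidden, n_out, sim, flavor_in = flavor,
                      density_in = density, seed = seed)
  net$W_in <- net$W_in * w_scale
  net
}

max_rel_dev <- function(a, b) {
  if (is.null(a) && is.null(b)) return(0)
  max(abs(a - b)) / max(abs(b), 1e-300)
}
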
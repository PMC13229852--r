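n_in: 116
n_hidden: 128
n_out: 20
recurrent: no
flavor_in: synaptic
flavor_rec: none
learn_weights: yes
learn_delays: yes
delay_init: uniform
density_in: 1.0
density_rec: 1.0
sim:
  alpha: 0.6
  kappa: 0.9900498
  v_th: 1.0
  dt: 10.0
  D_max: 25
  gamma_pd: 0.3
  sigma: 2.0
  kernel_k: 12
rates:
  lr_w: 0.0001
  lr_d: 0.01
  batch_size: 16
epochs: 60
seeds:
- 1
- 2
- 3
- 4
- 5
task:
  n_in: 4
  n_classes: 2
  T: 50
  dt: 10.0
  max_offset: 6
  spikes_per_channel: 4
  jitter_sd: 0.0
  planted_latencies:
  - 0
  - 0
  - 6
  - 2
  - 5
  - 1
  - 2
  - 2
  min_gap: 8
  tail_margin: 14
  seed: 1
n_train: 64
n_test: 32
shd_train: data/shd_train.h5
shd_test: data/shd_test.h5
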
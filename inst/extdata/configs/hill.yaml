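model: hill
theta: [1, 1, 4]
times: [0.1, 0.2, 3, 3.5, 4]
noise_sigma: 0
seed: 1
eps_eig: 1.0e-4
lambda: 1.0
design:
  initial_times: [0.25]
  grid: {from: 0, to: 4, n_points: 81}
  M_max: 20
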
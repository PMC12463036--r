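model: polynomial
theta: [1, 1, 1]
times: [1, 2, 3]
noise_sigma: 0
seed: 1
eps_eig: 1.0e-4
lambda: 1.0
design:
  initial_times: [1, 2, 3]
  grid: {from: 0, to: 4, n_points: 17}
  M_max: 10
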
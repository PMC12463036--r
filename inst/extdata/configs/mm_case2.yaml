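model: mm
observables: [P]
t_grid: {from: 0, to: 60, n_points: 25}
noise_sigma: auto
seed: 1
eps_eig: 1.0e-6
design:
  initial_times: [2.5]
  grid: {from: 0, to: 60, n_points: 61}
  M_max: 20
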
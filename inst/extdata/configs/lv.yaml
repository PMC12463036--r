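model: lv
theta: [0.55, 0.028, 0.024, 0.84]
t_grid: {from: 0, to: 20, n_points: 25}
noise_sigma: auto
seed: 1
eps_eig: 1.0e-6
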
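model: seir
observables: [I]
t_grid: {from: 0, to: 100, n_points: 25}
noise_sigma: auto
seed: 1
eps_eig: 1.0e-6
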
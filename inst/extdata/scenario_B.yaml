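# Working point B: repulsive coupling, non-stationary generalized splay
name: B
"N": 21
eta_mean: 2.0
delta_eta: 1.0e-3
kappa: -0.6283185307179586  # -0.2 * pi
nu: 20
kernel: {family: gamma, q: 2, tau: 0.8}
T: 1500
dt: 0.01
init_mode: uniform
perturbation: 0.01
models: [theta, ks]
expected_regime: generalized_splay
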
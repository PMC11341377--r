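# Working point A: attractive coupling, full synchronization
name: A
"N": 21
eta_mean: 2.0
delta_eta: 6.0e-3
kappa: -0.6283185307179586  # -0.2 * pi
nu: 20
kernel: {family: gamma, q: 2, tau: 0.5}
T: 1000
dt: 0.01
init_mode: uniform
perturbation: 0.01
models: [theta, ks]
expected_regime: synchronized
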
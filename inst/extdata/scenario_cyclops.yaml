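# Cyclops state: two 10-oscillator clusters plus a solitary oscillator,
# identical currents, delta-pulse limit
name: cyclops
"N": 21
eta_mean: 2.0
delta_eta: 0.0
kappa: -0.6283185307179586  # -0.2 * pi
nu: Inf
kernel: {family: gamma, q: 2, tau: 0.8}
T: 200
dt: 0.01
init_mode: near_cyclops
perturbation: 0.01
models: [ks]
expected_regime: cyclops
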
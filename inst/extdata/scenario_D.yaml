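# Working point D: repulsive coupling, asynchronous firing (QIF level).
# At N = 21 the asynchronous state may retain weak coherence, so no
# regime label is asserted.
name: D
"N": 21
eta_mean: 2.0
delta_eta: 6.0e-3
kappa: -0.6283185307179586  # -0.2 * pi
nu: 100000
kernel: {family: gamma, q: 4, tau: 0.41}
T: 500
dt: 0.01
init_mode: uniform
perturbation: 0.01
models: [qif, ks]
v_th: 1.0e5
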
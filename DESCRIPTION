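Package: ksreduce
Title: Kuramoto-Sakaguchi Reduction of Quadratic Integrate-and-Fire
    Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reduces finite-size networks of quadratic integrate-and-fire
    (QIF) and theta neurons with general synaptic activation kernels to
    the Kuramoto-Sakaguchi phase model. Provides the gamma-family
    synaptic kernel and its complex Fourier coefficients, finite-width
    pulse shapes with hypergeometric Fourier coefficients and their
    delta-pulse limit, the self-consistent fast frequency, closed-form
    criteria for attractive versus repulsive coupling, fixed-step
    simulators for the QIF, theta-neuron, Winfree-form phase, and
    Kuramoto-Sakaguchi models with a linear synaptic cascade, and
    diagnostics (Kuramoto order parameters, firing rates, cluster
    detection) that classify synchronized, generalized splay, and cyclops
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
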
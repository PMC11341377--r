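---
title: "Reducing QIF neuron networks to the Kuramoto-Sakaguchi model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing QIF neuron networks to the Kuramoto-Sakaguchi model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksreduce)
```

## The three model levels

The package works with a globally coupled network of $N$ Type I spiking
neurons at three levels of description.

**QIF level.** Each membrane potential obeys
$$\dot v_n = v_n^2 + \eta_n + \varkappa S(t), \qquad
v_n \ge v_{th} \;\Rightarrow\; v_n \leftarrow v_r,$$
with constant excitability currents $\eta_n > 0$ (every neuron
intrinsically oscillatory), a common synaptic weight $\varkappa$
($\varkappa < 0$ is inhibitory, which for sharp pulses is the
*attractive* sign), and a mean synaptic activity $S(t)$ obtained by
filtering the population spike train through a normalized kernel
$$G(t) = \frac{(t/\tau)^q e^{-t/\tau}}{q!\,\tau}, \qquad t \ge 0,$$
the Green's function of the cascade operator $(\tau\,d/dt + 1)^{q+1}$.
The order $q$ controls the synaptic latency — the kernel peaks at
$t_{\max} = q\tau$, with mean $(q+1)\tau$, variance $(q+1)\tau^2$ and
skewness $2/\sqrt{q+1}$ — while $\tau$ sets the rise/decay time scale.
$q = 0$ is the exponential synapse and $q = 1$ the classical alpha
function.

**Theta level.** The smooth change of variables $v = \tan(\theta/2)$
(exact in the limit $v_{th} = -v_r \to \infty$) yields the theta-neuron
network
$$\dot\theta_n = (1 - \cos\theta_n) + (1 + \cos\theta_n)(\eta_n +
\varkappa S),$$
where a spike is the upward crossing of $\theta = \pi$ and the synaptic
source is the population mean of a smooth pulse
$P_\nu(\theta) = p_\nu (1 - \cos\theta)^\nu$ of integer sharpness
$\nu$. The normalization $p_\nu = 2^\nu (\nu!)^2 / (\pi (2\nu)!)$ fixes
the circle integral of $P_\nu$ at 2, the weight of its
$\nu \to \infty$ limit, a Dirac comb at the spike phase. With
delta pulses and infinite threshold the theta and QIF levels are the
same model.

**Reduced (Kuramoto-Sakaguchi) level.** A second change of variables
$2\tan(\theta/2) = \Omega \tan(\varphi/2)$ makes each uncoupled neuron
rotate uniformly at a rate $\Omega$. For weak coupling, averaging over
the fast rotation leaves slow phases $\phi_n = \varphi_n - \Omega t$
governed by
$$\dot\phi_n = \omega_n + \frac{K}{N} \sum_{n'}
\sin(\phi_{n'} - \phi_n - \alpha),$$
with explicitly computable parameters:
$$\omega_n = \frac{2(\eta_n - \Omega^2/4 + \varkappa Q_{\nu 0})}{\Omega},
\qquad K = \frac{2 \varkappa |G_1| Q_{\nu 1}}{\Omega}, \qquad
\alpha = -\arg G_1 - \frac{\pi}{2}.$$
Here $Q_{\nu 0}$ and $Q_{\nu 1}$ are the first two Fourier
coefficients of the pulse seen in the rotating phase (real, with
$Q_{\nu 1} \le 0$, so $K$ and $\varkappa$ always have opposite signs),
and $G_1 = (1 + i\Omega\tau)^{-(q+1)}$ is the kernel's complex Fourier
coefficient at the rotation frequency. $\Omega$ itself is fixed
self-consistently by requiring $\operatorname{mean}(\omega_n) = 0$,
i.e. by solving
$\langle\eta\rangle - \Omega^2/4 + \varkappa Q_{\nu 0}(\Omega) = 0$
(`solve_omega()`); in the delta-pulse limit
$Q_{\infty\ell} = (-1)^\ell \Omega / 2\pi$ and the equation has the
closed root $\Omega = (\varkappa + \sqrt{\varkappa^2 +
4\pi^2\langle\eta\rangle})/\pi$.

The practical payoff is the sign of $K\cos\alpha$: positive means
attractive coupling (full synchronization is stable), negative means
repulsive coupling (splay-type and cyclops states). For a gamma kernel
and inhibitory coupling this reduces to
$\sin\!\big((q+1)\arctan(\tau\Omega)\big) > 0$, i.e. alternating bands
in the $\tau\Omega$ axis with endpoints $\tan(k\pi/(q+1))$
(`is_attractive()`, `attractive_intervals()`, `region_map()`). Over
the full $\tau\Omega$ axis there are $\lfloor q/2 \rfloor + 1$ such
bands; on the physical half-axis $\tau\Omega > 0$ the first band is
$(0, \tan(\pi/(q+1)))$, unbounded for $q = 0$.

## Evaluating the coefficients

**Pulse coefficients $Q_{\nu\ell}$.** The closed form is a finite sum
of Gauss hypergeometric terms,
$${}_2F_1\!\left(\ell + 1,\, \ell - m + \tfrac12;\, \nu + \ell + 1;\,
1 - \tfrac{\Omega^2}{4}\right), \quad m = 0, \dots, \ell,$$
with binomial and gamma-function prefactors evaluated in log space.
The series for ${}_2F_1$ converges geometrically for argument
$|z| < 1$; negative arguments ($\Omega > 2$) are mapped into $(0, 1)$
by the Pfaff transformation. Because the third parameter grows with
$\nu$, the series converges in a handful of terms even at
$\nu = 10^5$, so no separate asymptotic branch is needed near the
delta limit. When $\Omega$ is small the argument approaches 1 and the
series degenerates; `pulse_fourier()` then falls back automatically
(with a message) to adaptive quadrature of the defining integral. The
quadrature splits the domain near $\varphi = \pi$, where the integrand
concentrates in a region of width $\sim 1/\sqrt{\nu}$.

The closed form and the quadrature are verified against each other to
$10^{-8}$ over a grid of $(\ell, \nu, \Omega)$ in the test suite; since
the quadrature integrates the normalized pulse directly, this agreement
also validates the reconstructed constant $p_\nu$.

**Kernel coefficients $G_\ell$.** The gamma family has the closed form
$(1 + i\ell\Omega\tau)^{-(q+1)}$; tabulated kernels are supported
through the quadrature path only. The quadrature horizon in the
dimensionless lag is $(q+1) + 12\sqrt{q+1} + 30$: the first two terms
track the density's mean and spread, and the fixed extension keeps the
truncated tail (bounded by $u^q e^{-u}/q!$) below $10^{-14}$ even for
the exponential kernel, whose tail decays slowly relative to its mean.

## Integration schemes

All smooth phase models (theta, rotating-phase/Winfree form, reduced
KS) use classical fixed-step RK4, default $dt = 0.01$. Spike times are
located inside a step by linear interpolation of the crossing of the
spike phase, online at full step resolution.

**Synaptic cascade.** $S(t)$ is generated by the factorized cascade
$\tau \dot u_1 + u_1 = \text{input}$, $\tau \dot u_{k+1} + u_{k+1} =
u_k$, $S = u_{q+1}$, whose Green's function is exactly the gamma
kernel. For the smooth-pulse models the cascade is integrated jointly
with the phases by RK4. In the delta-pulse and QIF cases the input is
a sum of spike impulses: between impulses the homogeneous cascade is
propagated *exactly* (the matrix exponential of the bidiagonal stage
system has a closed form), and each spike adds $1/(N\tau)$ to the
first stage at the end of the step in which it occurred. A unit
impulse therefore reproduces `gamma_kernel_value(t)/N` to machine
precision, which the test suite checks at $10^{-6}$.

**QIF stepping.** The membrane equation $\dot v = v^2 + c$ blows up in
finite time, so explicit RK4 cannot carry a neuron from
$v_r = -10^5$ to $v_{th} = +10^5$: the very first stage of a step
overshoots past $+\infty$. Instead, each step freezes the drive at its
midpoint value, $c_n = \eta_n + \varkappa S(t + dt/2)$, and advances
the resulting Riccati equation with its exact solution
($v \mapsto \sqrt{c}\,\tan(\sqrt{c}\,s + \arctan(v/\sqrt{c}))$ for
$c > 0$, with hyperbolic and degenerate branches for $c \le 0$).
Threshold crossings then have closed-form times within the step, and
the uncoupled inter-spike interval is reproduced to $2\times10^{-5}$
at $dt = 0.01$. The optional `pass_through` refractory mode adds the
leading-order transit time $1/v_{th} + 1/|v_r|$ through the spike
singularity before placing the neuron at $v_r$, approximating
large-$N$ schemes that account for this passage; it is treated as a
qualitative device and only its ordering effect on firing is tested.

**Convergence.** For the smooth models, halving $dt$ reduces
spike-time error by well over the factor 3.5 asserted in the tests
(the interpolation of the crossing is second-order, the integrator
fourth-order). The QIF propagator is exact in time for frozen drive;
its error is set by the $O(dt^2)$ midpoint freezing of $S$.

## Study conditions: generators and scenarios

Synthetic inputs are pure functions of a seed. `make_eta()` draws the
currents uniformly from $[\bar\eta - \delta\eta/2, \bar\eta +
\delta\eta/2]$; `make_initial_phases()` provides uniform draws on
$[-\pi, \pi]$, a near-synchronous cluster, or a near-cyclops
configuration: two $m$-clusters at $\pm\arccos(-1/2m)$ plus a solitary
oscillator at 0 — the unique symmetric three-cluster arrangement with
exactly vanishing first-order order parameter — each phase perturbed
uniformly by a configurable half-width (default 0.01 rad).

The bundled working points (`scenario_preset()`) all use $N = 21$,
$\bar\eta = 2$, $\varkappa = -0.2\pi$:

| scenario | $q$ | $\tau$ | $\nu$ | $\delta\eta$ | coupling | long-time state |
|---|---|---|---|---|---|---|
| A | 2 | 0.50 | 20 | $6\times10^{-3}$ | attractive | synchronized |
| B | 2 | 0.80 | 20 | $10^{-3}$ | repulsive | generalized splay |
| C | 4 | 0.15 | $10^5$ | $6\times10^{-3}$ | attractive | synchronized firing (QIF) |
| D | 4 | 0.41 | $10^5$ | $6\times10^{-3}$ | repulsive | asynchronous firing (QIF) |
| cyclops | 2 | 0.80 | $\infty$ | 0 | repulsive | two 10-clusters + solitary |

**Horizons.** The approach to the long-time state is governed by the
reduced model's own rate $|K\cos\alpha|$: about 0.0147 at point A and
0.0038 at point B, i.e. e-folding times of roughly 70 and 260 time
units. Horizons are therefore set to roughly ten relaxation times
(A 1000, B 1500, C 200, D 500), not to a fixed common value — a run an
order of magnitude shorter than the relaxation time would classify the
transient, not the attractor. Scenario A uses about fifteen relaxation
times because the per-neuron comparison between model levels (below)
needs the locked state itself, not just $r_1$ near 1. The cyclops
scenario starts near the state whose persistence it probes and uses
$T = 200$. Classification discards the first half of the horizon as
transient.

**Classification.** Regimes are labelled from the post-transient
window in a common coordinate (theta-model phases are mapped to the
rotating phase; KS slow phases differ from it only by a global
rotation, which no diagnostic here sees): `synchronized` if the
time-mean $r_1 > 0.95$, `cyclops` if the cluster pattern $(m, m, 1)$
holds on at least 90% of samples (single-linkage on the circle,
tolerance 0.05 rad), `generalized_splay` if time-mean $r_1 < 0.1$,
otherwise `other`. The 0.95 / 0.1 / 0.05 / 90% figures are heuristic
thresholds chosen once and recorded in every report; the underlying
qualitative criteria (order parameters near 1 or 0, a persistent
three-cluster pattern) are what they operationalize. At $N = 21$ the
splay state's finite-size fluctuations keep $r_1$ at the few-percent
level, well below the 0.1 threshold once settled.

**Cross-model agreement.** `run_scenario()` simulates the requested
levels from one seeded initial state mapped through the coordinate
changes, and reports (i) the maximum post-transient gap between the
first-order order-parameter series and (ii) a settled per-neuron
statistic: over the final tenth of the run, the time-mean of the
worst-neuron mismatch of phase differences $\theta_n - \theta_N$
between the model and the mapped reduction. The time-mean is
deliberate: while a synchronized cluster sweeps the spike phase, the
theta coordinate momentarily stretches tiny timing offsets, so the
instantaneous worst-case spikes even when the locked configurations
agree; in the slow coordinate the settled mismatch at point A is
$\sim0.02$ rad. Mid-transient, individual neurons may desynchronize
in different orders in the two models — the reduction guarantees
per-neuron trajectory tracking only for weak coupling over times
$O(1/\varepsilon)$ — so per-neuron agreement is asserted for the
settled state, while order parameters and regime labels are compared
over the whole post-transient window.

## What the tests do and do not establish

The synthetic conditions exercise all-to-all coupling, uniform current
heterogeneity, a single gamma kernel per run, and no noise, topology
or plasticity — deliberately matching the model class of the
reduction. Passing tests therefore demonstrate internal consistency
(closed forms vs quadrature, cross-level dynamical equivalence,
predicted regime boundaries) under those conditions; they say nothing
about conductance-based synapses, structured networks, or
noise-driven regimes. Known limitations worth keeping in mind:

* the reduction is leading-order in the coupling; at $|K|$ comparable
  to $\Omega$ the phase model drifts from the spiking models long
  before the attractor is reached;
* point D at $N = 21$ can retain weak coherence (its label is not
  asserted; the repulsive sign classification is);
* `pass_through` is a leading-order account of the finite-threshold
  transit time, not the full large-$N$ refractory algorithm;
* region-map cells inherit the root-finder's failure modes; cells
  where the frequency equation has no admissible root are `NA`, not
  silently dropped.

## A worked reduction

```{r example, eval = FALSE}
eta <- make_eta(21, eta_mean = 2, delta_eta = 6e-3, seed = 1)
net <- network_params(eta, kappa = -0.2 * pi, nu = 20,
                      kernel = synaptic_kernel(q = 2, tau = 0.5))
ks <- reduce_to_ks(net)
ks
is_attractive(q = 2, tau = 0.5, Omega = ks$Omega, kappa = -0.2 * pi)
attractive_intervals(q = 2)

rep <- run_scenario(scenario_preset("cyclops"), seed = 1)
rep$regimes$ks
```
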
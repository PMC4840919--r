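---
title: "Matched-variance diffusion approximations for adaptive integrate-and-fire neurons"
author: "adexfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-variance diffusion approximations for adaptive integrate-and-fire neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adexfp)
```

# The model

The package computes steady-state and linear-response statistics of the
adaptive exponential integrate-and-fire (AdEx) neuron driven by stochastic
synaptic input.  In per-capacitance units ($C_m \equiv 1$, so $g_L = 1/\tau_m$;
voltages in mV, times in ms, rates in kHz) the membrane potential $V$ and
adaptation current $w$ obey

$$
\frac{dV}{dt} = \frac{E_L - V}{\tau_m} + \psi(V) - w + I(t), \qquad
\tau_w \frac{dw}{dt} = a\,(V - E_L) - w,
$$

with the exponential spike-initiation current
$\psi(V) = (\Delta_T/\tau_m)\, e^{(V - V_T)/\Delta_T}$, and the
threshold–reset rule: when $V \ge V_{th}$ a spike is recorded, $V \to V_{re}$
and $w \to w + b$.  The per-capacitance convention is used because the
default parameter set specifies $a/C_m$, $b/C_m$ and the synaptic weights
directly in these units; carrying $C_m$ separately would add a redundant
degree of freedom.

Two synaptic input models are provided.

* **Temporally uncorrelated**: excitatory and inhibitory spikes arrive as
  homogeneous Poisson processes (rates $r_e$, $r_i$) with delta-function
  synaptic currents of weight $J_e > 0$, $J_i < 0$.
* **Temporally correlated**: the presynaptic rates $\nu_x(t)$ follow
  Ornstein–Uhlenbeck dynamics (mean $r_x$, SD $\sigma_\nu$, timescale
  $\tau_\nu$), and arrivals are filtered by unit-area kernels — a
  single-exponential EPSC (decay $\tau_e$) and a difference-of-exponentials
  IPSC (rise $\tau_{r,i}$, decay $\tau_{d,i}$), mimicking AMPA- and
  GABA$_B$-like kinetics.

The defaults (`adex_defaults()`) are $\tau_m = 15$, $E_L = V_{re} = -72$,
$\Delta_T = 1$, $V_T = -55$, $V_{th} = -45$, $a = 0.15$ kHz, $b = 0.025$
mV·kHz, $\tau_w = 50$ ms, $J_e = 0.4$, $J_i = -0.75$ mV, $r_e = 10$,
$r_i = 2$ kHz, $\tau_e = 4$, $\tau_{r,i} = 1$, $\tau_{d,i} = 6$,
$\tau_\nu = 10$ ms, $\sigma_\nu = 0.1$ kHz.

# Diffusion approximations

For uncorrelated input, the classic diffusion approximation replaces $I(t)$
by $\mu_I + \sqrt{2 D_I}\,\eta(t)$ with $\mu_I = J_e r_e + J_i r_i$ and
$D_I = (J_e^2 r_e + J_i^2 r_i)/2$, matching the first two infinitesimal
moments of the shot noise.  The **quasi-static** approximation further
replaces $w(t)$ by its stationary mean $\mu_w$, reducing the model to one
dimension; it ignores all *fluctuations* of the adaptation current.

The **matched-variance** approximation corrects the dominant part of that
error.  The free (non-spiking) linearized membrane–adaptation system has
stationary voltage variance

$$
\operatorname{var}(U) \;=\; D_I\,\tau_m
\left[\,1 - \frac{a}{a + 1/\tau_m}\cdot\frac{\tau_m}{\tau_m + \tau_w}\right],
$$

whereas the quasi-static reduction gives $D_I \tau_m$ regardless of $a$ and
$\tau_w$.  Rescaling the noise intensity to
$D_{\mathrm{eff}} = D_I \times [\cdot]$ (the bracketed factor,
`matched_variance_factor()`) makes the one-dimensional model reproduce the
correct sub-threshold variance.  The factor lies in $(0, 1]$, decreases with
the voltage-coupling $a$ and increases with $\tau_w$: adaptation feedback
matters most when it is strong and fast.

For temporally correlated input the same matching is done in the frequency
domain.  With membrane filter $\tilde K_v = \tau_m/(1 + 2\pi i f \tau_m)$ and
adaptation filter $\tilde K_w = 1/(1 + 2\pi i f \tau_w)$, the closed-loop
transfer from current to free membrane potential is
$K_{\mathrm{eff}} = \tilde K_v/(1 + a \tilde K_v \tilde K_w)$, and

$$
D_{\mathrm{eff}} = \frac{1}{\tau_m}\int_{-\infty}^{\infty}
\tilde C_{II}(f)\, |K_{\mathrm{eff}}(f)|^2 \, df,
$$

where $\tilde C_{II}$ combines the Lorentzian spectra of the synaptic
kernels and of the OU rate fluctuations (`input_psd_correlated()`).  The
integral is evaluated by adaptive quadrature on $[0, \infty)$ doubled by
evenness (`stats::integrate`, relative tolerance $10^{-9}$); in the limit of
vanishing input timescales it reduces to
$D_I \times$ `matched_variance_factor()`, which the test suite verifies to
1%.

```{r deff}
p <- neuron_params()
inp <- uncorrelated_input()
matched_variance_factor(p)
d_eff_correlated(p, correlated_input())
```

# Threshold integration

Either approximation leaves a one-dimensional Fokker–Planck problem for the
stationary density $P(V)$ with drift
$F(V) = (E_L - V)/\tau_m + \psi(V) - \mu_w + \mu_I$ and noise intensity $D$.
`steady_state()` solves it by threshold integration: the flux is
$j(V) = r_0$ on $(V_{re}, V_{th})$ and $0$ below the reset (the reset
re-injection is a flux step at the $V_{re}$ node), and the unnormalized
density obeys $D\,p' = F p - j$ with $p(V_{th}) = 0$, integrated backward
from the threshold.  The rate is recovered from normalization,
$r_0 = 1/\int p \, dV$.

Three schemes are provided on the same (refinable, non-uniform) mesh:

* `euler` — explicit first-order steps on the density ODE.  Unstable unless
  $|F|\,\Delta v / D$ is small everywhere, which near the exponential
  spike-initiation region requires extremely fine meshes; on coarse meshes
  the density blows up and the predicted rate collapses to zero (reported
  via the `degenerate` flag).
* `midpoint` — per-cell exact integrating factor with the drift frozen at
  the cell midpoint (the previously standard "modified Euler" scheme).
* `simpson` — per-cell integrating factor with the exponent
  $\int F/D\,dV$ and the inhomogeneous integral evaluated by 3-point
  Simpson rules.  For this scheme the normalization mass and the voltage
  moment are also accumulated by per-cell Simpson quadrature (using
  half-cell midpoint density values); with the trapezoid rule the shared
  $O(\Delta v^2)$ quadrature error would dominate both schemes and mask the
  higher order of the Simpson variant.

Numerical choices: the mesh spans $[V_{lb}, V_{th}]$ with
$V_{lb} = E_L - 40$ mV by default (exposed as a knob; the solver warns when
$P(V_{lb}) > 10^{-12} \max P$, as happens for strongly scaled-up synaptic
weights, where a deeper bound should be used), base spacing
$\Delta v = 10^{-2}$ mV and tenfold refinement within 1 mV of $V_{re}$ and
$V_{th}$.  This default sits on the convergence plateau of
`convergence_study()`: refining to the $10^{-4}$ mV uniform reference mesh
changes the rate by under $10^{-6}$ relative.  The exponent of $\psi$ is
clamped at $+50$ so Monte Carlo trajectories between threshold crossings
cannot overflow; the Fokker–Planck solver itself never evaluates above
$V_{th}$.  In the leaky (Δ_T = 0) limit the solver agrees with the closed-form
Siegert first-passage rate to better than $10^{-4}$ relative (test suite).

# Self-consistent adaptation

The mean adaptation current at the fixed point satisfies
$\mu_w = a(\mu_V - E_L) + \tau_w b\, r_0$, while $(r_0, \mu_V)$ depend on
$\mu_w$ through the Fokker–Planck solve.  `solve_self_consistent()` iterates
the damped map
$\mu_w \leftarrow (1-\lambda)\mu_w + \lambda\,[a(\mu_V - E_L) + \tau_w b r_0]$
until successive rates change by less than $10^{-6}$ kHz.  The loop gain of
the undamped map is approximately $a\,\tau_m$ (the voltage response to a
change in mean adaptation current is $\approx -\tau_m$), so any fixed
damping $\lambda \ge 1/(1 + a\tau_m)$ can oscillate or diverge for strong
voltage coupling — at $a = 0.3$ kHz and $\tau_m = 15$ ms the gain is 4.5 and
$\lambda = 0.5$ diverges.  The default is therefore the adaptive choice
$\lambda = \min(0.5,\ 1/(1 + a\tau_m))$, which makes the damped map
contractive for every adaptation strength; it reduces to the conventional
$\lambda = 0.5$ for weak coupling.

```{r fixedpoint}
fp <- solve_self_consistent(p, diffusion_spec(p, inp))
fp
```

# Linear response

`susceptibility_at()` computes the transfer function $S_r(f)$ from a weak
uniform current modulation to the firing-rate modulation.  About a converged
base state it first solves the modulated Fokker–Planck system for the
*non-adaptive* responses $A_r(f)$ (rate) and $A_V(f)$ (mean voltage), then
closes the adaptation loop through the linearized mean dynamics,
$\hat w = (a \hat V + \tau_w b \hat r)/(1 + 2\pi i f \tau_w)$, giving
$S_r = A_r / (1 + L)$ with $L = (a A_V + \tau_w b A_r)/(1 + 2\pi i f\tau_w)$.
The loop produces the characteristic low-frequency resonance of adapting
neurons; without adaptation the low-frequency response is flat.

The modulated system is *not* integrated backward like the steady state:
its homogeneous solutions oscillate and grow like
$\exp(\sqrt{\omega/2D}\,|V|)$, so shooting loses all precision above a few
hundred Hz on meshes tens of mV deep.  Instead the same per-cell Simpson
integrating-factor relations are assembled into one block-tridiagonal linear
system (unknowns $(\hat p_i, \hat J_i)$ per node; absorbing condition at
$V_{th}$, reflecting condition $\hat J = 0$ at $V_{lb}$, re-injection as a
rank-one border resolved by the Sherman–Morrison identity) and solved
globally.  This is unconditionally stable; the result is independent of
$V_{lb}$ across the full 0–2 kHz band.  At $f \to 0$ the discrete operator
becomes singular (the stationary normalization mode), so the zero-frequency
value is obtained instead as a centred finite difference of the full
self-consistent rate with respect to $\mu_I$ (`susceptibility_zero()`),
with the fixed point converged to $10^{-12}$ kHz so the iteration tolerance
is far below the finite-difference signal.  The two routes agree to well
under 1% at the defaults (test suite).

## Coarse evaluation and interpolation

Inverse-FFT products need $S_r$ on a uniform grid (default 0–2 kHz in 0.1 Hz
steps, 20 001 points), but a threshold-integration solve per frequency is
wasteful because $S_r$ is smooth on a log scale.  `susceptibility_curve()`
evaluates 30 frequencies spaced evenly in $\log f$ between 0.01 Hz and
2 kHz, prepends the finite-difference $f = 0$ value, and interpolates the
real and imaginary parts separately with monotone piecewise-cubic Hermite
polynomials.  Two refinements keep the 30-point claim honest: interpolation
is done against $\log f$ (the nodes are equally spaced there), and the known
membrane rolloff $1/(1 + 2\pi i f \tau_m)$ is factored out first, so the
interpolated residual is nearly flat at both ends of the grid.  Re/Im
interpolation (rather than magnitude/phase) preserves linearity and avoids
phase-unwrapping artifacts.  The interpolated curve reproduces direct
evaluation to well under 1% maximum relative deviation at the defaults
(test suite).

## Products

* **Spike-triggered average.**  For an added weak white-noise current of
  intensity $D_n$, $\tilde C_{us}(f) = 2 D_n S_r(f)$ and
  $\mathrm{STA} = (2 D_n / r_0)\, \mathcal{F}^{-1}[S_r^*]$
  (`sta_from_susceptibility()`; Hermitian extension with the zero-frequency
  and Nyquist bins forced real, so the time-domain imaginary residue is at
  machine precision).  Note that even a weak probe shifts the operating
  point — the white noise adds $D_n$ to the diffusion coefficient — so the
  base state must be solved with `diffusion_spec(..., D_extra = D_n)`.
* **Shared-input pair correlations.**  Two identical neurons sharing a
  fraction $c$ of their excitatory presynaptic spikes have, to first order
  in $c$, spike-train cross-spectrum
  $\tilde C_{s_1 s_2}(f) = |S_r(f)|^2\, c\, J_e^2\, r_e$
  (`pair_cross_spectrum()`); the cross-covariance follows by inverse FFT.

# The Monte Carlo oracle

`simulate_uncorrelated()`, `simulate_correlated()` and
`simulate_shared_pair()` implement the exact two-dimensional model with a
compiled forward-Euler kernel (time bin $dt = 0.1$ ms by default; 65 s per
run with the first 5 s discarded; repeats seeded as `seed + repeat - 1`, so
a fixed seed gives bit-identical output).  Design choices, made where the
protocol leaves freedom:

* arrival counts per bin are Poisson with mean $r\,dt$ (exact for
  homogeneous rates, correct to $O(dt)$ for OU-modulated rates);
* the OU rate state evolves unclipped by its exact per-bin update and is
  clipped at zero only when drawing arrivals, preserving its spectrum;
* a spike is registered at the first bin where the updated $V \ge V_{th}$,
  with no sub-bin interpolation — overshoot-preserving resets are
  meaningless for the exponential model, whose $V$ is typically far above
  threshold at detection;
* initial conditions $V(0) = E_L$, $w(0) = 0$, $\nu_x(0) = r_x$, synaptic
  filter states at their stationary means; the burn-in makes these
  immaterial.

Spectral estimation (`estimate_csd()`) uses Hann-windowed Welch segments of
$2^{14}$ bins with 50% overlap and overall mean subtraction, normalized so
that white noise of intensity $D$ has a flat two-sided density $2D$ and the
integrated density recovers the variance.

The simulator *emulates the model, not a biological recording*: synapses
are current-based with fixed kernels, rates are stationary OU fluctuations,
and there is no conductance shunting, NMDA-like voltage dependence,
synaptic depression or non-Poisson presynaptic structure.  Agreement of the
approximations with this oracle therefore bounds only the reduction error
of the one-dimensional Fokker–Planck description, not the realism of the
AdEx model itself.

A property of the oracle worth knowing when reading the validation numbers:
forward Euler at $dt = 0.1$ ms biases the simulated rate by a few percent in
two regimes.  At high rates the bin-resolution threshold detection and the
slowed traversal of the exponential upswing delay each spike by a fraction
of a bin; in the fluctuation-driven regime the Euler update inflates the
stationary voltage variance by $\approx dt/2\tau_{\mathrm{eff}}$ with
$\tau_{\mathrm{eff}} = \tau_m/(1 + a\tau_m)$, which is exponentially
amplified in the rate when the threshold sits several standard deviations
away.  The validation protocols pin $dt = 0.1$ ms, so the reported maxima
over the adaptation grid include this protocol bias on top of the
approximation error; the test suite's step-halving check quantifies the
effect at the defaults.

# Validation problem sizes

The test suite validates every module end-to-end with fixed seeds: the
(a, τ_w) adaptation grid at 5 × 4 points with 4 × 65 s of simulation per
point; the weight-scaling sweep at $c \in \{0.5, 1, 2, 4\}$ with 10 × 65 s
per scaling; free-membrane variance checks with 6 repeats of 35 s
(uncorrelated) and 25 s at $dt = 0.025$ ms (correlated, where the Euler
filter bias would otherwise intrude); STA and pair-covariance comparisons
with 10 × 65 s.  `scripts/acceptance.R` uses the same protocols with
rate-adaptive repeat counts (8–96 runs per grid point, targeting several
thousand spikes each) so its reported maxima are dominated by systematic
rather than sampling error.  The convergence study compares schemes at base
spacings $\{0.1, 0.05, 0.02, 0.01\}$ mV against a Simpson reference on the
$10^{-4}$ mV uniform mesh ($\sim 7 \times 10^5$ nodes).

Comparisons of binned Monte Carlo estimates with band-limited inverse-FFT
predictions exclude the two 1-ms lag bins straddling zero lag in the STA:
the spike-triggered average is discontinuous there (the input after a spike
is uncorrelated with it), and a truncated Fourier representation cannot be
compared pointwise across a jump.

# Known limitations

* For temporally correlated input at the default timescales the
  matched-variance approximation retains substantial rate errors (tens of
  percent); it degrades further as input timescales grow, although it
  dominates the quasi-static approximation throughout.
* Spike-train power spectra and Fano factors of the *output* train are out
  of scope; the strong, slow adaptation makes the output non-renewal.
* Strong spike-based adaptation (large $b$, small $\tau_w$) is treated only
  through the mean $\mu_w$, and the reset-induced coupling of $V_{re}$ into
  $w$ is ignored, so accuracy degrades for very negative reset potentials.
* The full two-dimensional Fokker–Planck solve, conductance-based or
  NMDA-type synapses and nonlinear adaptation dynamics are not implemented.
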
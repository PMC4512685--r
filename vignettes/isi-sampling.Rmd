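---
title: "Interspike-interval sampling with EIF and LIF neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspike-interval sampling with EIF and LIF neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isisampler)
```

## The idea

During cortical UP states a neuron's membrane potential sits close to the
firing threshold in a high-conductance regime, and it fires sparsely and
irregularly.  `isisampler` studies a quantitative interpretation of this
state: the neuron acts as a *random sampler*, each spike carrying as its
analog value the length of the preceding interspike interval (ISI), so that
a spike train is a stream of i.i.d. draws from an ISI distribution
$p(t)$.  A presynaptic population can then *choose* the distribution being
sampled by shaping the input current, and the question the package answers
quantitatively is how faithfully a given target distribution survives the
trip through the neuron's biophysics — and why the exponential
integrate-and-fire (EIF) neuron is a much better transducer than the leaky
integrate-and-fire (LIF) neuron when the voltage baseline is high.

## Renewal scaffolding

For a renewal process, hazard $h(t)$, survivor $S(t)$ and ISI density
$p(t)$ are linked by
$$S(t) = \exp\Big(-\int_0^t h\Big), \qquad p(t) = S(t)\,h(t),
\qquad h = p/S .$$
`survivor_from_hazard()`, `isi_from_hazard()` and `hazard_from_isi()`
implement these transforms on a uniform grid with cumulative trapezoid
integration (error $O(dt^2)$, consistent with the smooth signals used
throughout).  `hazard_from_isi()` deliberately recomputes $S$ from the
density rather than trusting a stored survivor, so that the
forward/backward pair is a genuine inverse; it refuses windows on which the
recomputed survivor is exhausted (values below $10^{-300}$ are clamped to
zero).  `sample_isis()` draws ISIs by inverse-transform sampling of
$1 - S$ and insists that the window hold at least 99% of the probability
mass; `recommend_window()` suggests $T = -\ln(0.01)/h_0$ for a baseline
hazard $h_0$.

## Membrane dynamics and stochastic firing

The EIF membrane equation, in current-density units ($I^* = I/C_m$),

$$\dot V = -\frac{V - E_L}{\tau_m}
  + \frac{\Delta_T}{\tau_m} e^{(V - V_T)/\Delta_T} + I^*(t),$$

is integrated with a third-order Runge–Kutta scheme at a default step of
$dt = 0.05$ ms.  The LIF is the $\Delta_T \to 0$ limit.  Spiking is
*stochastic*: a hazard depends exponentially on the (optionally filtered)
distance from threshold,

$$h(t) = \frac{1}{K\tau_m}
  \exp\!\Big(\frac{(\mathcal{K} * (V - V_T))(t)}{\Delta_T}\Big),$$

with the spiking-determinism parameter fixed at 3 mV for *both* models so
they differ only in their subthreshold dynamics, and $K$ calibrated so the
hazard at $V = V_T$ is 10 Hz (a typical UP-state rate).  This escape-noise
hazard stands in for the diffusive synaptic noise of real UP states;
diffusive noise itself (fluctuating $V$, deterministic threshold) is out of
scope.  For a clean density computation the trajectory is deterministic —
a reset to $V_r$ happens only if $V$ crosses the peak $V_p$ (EIF) or the
threshold $V_T$ (LIF), detected at the first grid point at or above the
criterion (no sub-step interpolation, error $O(dt)$).

Default parameters (`neuron_params()`, `hazard_params()`):

| parameter | value | unit | meaning |
|---|---|---|---|
| $C_m$ | 0.281 | nF | membrane capacitance |
| $g_L$ | 150 (high) / 30 (low) | nS | leak conductance, selects the regime |
| $\tau_m$ | 1.9 / 9.4 | ms | $C_m/g_L$ |
| $E_L$ | $-70.6$ | mV | leak reversal |
| $V_T$ | $-50.4$ | mV | threshold |
| $\Delta_T$ | 3 (EIF) / 0 (LIF) | mV | slope factor |
| $V_p$ | $-40.4$ | mV | peak (spike detection, EIF) |
| $V_r$ | $V_0$ | mV | reset; every baseline resets to itself |
| $K$ | 53.4 / 10.7 | — | $1/(10\,\mathrm{Hz}\cdot\tau_m)$ |
| $dt$ | 0.05 | ms | integration step |

The reset convention $V_r = V_0$ (and initial condition $V(0) = V_0$)
mirrors the small afterhyperpolarization of regular-spiking cortical cells
during UP states, and makes the hazard start unperturbed at a spike —
the initial condition the analytic machinery assumes.

## Targets and their encoding as current

A target ISI distribution is a multiplicatively modulated exponential,
$p_\mathrm{in}(t) = p_0(t)\,\Delta p_\mathrm{in}(t)$ with
$p_0 = h_0 e^{-h_0 t}$.  `make_log_modulation()` builds
$\ln \Delta p_\mathrm{in}$ as a sum of `n_sinusoids` unit-amplitude
sinusoids at equidistant frequencies (endpoints included; a single
sinusoid sits at `f_lo`), with phases uniform on $[0, 2\pi)$ from a seed.
Two presets reproduce the standard designs: *low* band, 60 sinusoids on
[10, 100] Hz; *high* band, 60 sinusoids on [100, 200] Hz.

The raw sum is affinely mapped **in log space** so that
$\Delta p_\mathrm{in}$ spans exactly $[1 - r_{\Delta p},\, 1 + r_{\Delta p}]$
on the window.  A zero-mean centering plus pure scaling cannot achieve this
range exactly (the interval is asymmetric in log space), so the package
realizes the range exactly and accepts an approximate centering instead;
the residual effect is a small systematic negative bias of the
seed-averaged $\Delta p_\mathrm{in}$ (about 4% below 1 at
$r_{\Delta p} = 0.3$), verified in the tests.

`encode_target_current()` inverts the small-signal relationship between
current and log-density: for the EIF,

$$I^*(t) = \frac{V_0 - E_L}{\tau_m}
 + \Delta_T\Big[-(K - 1)h_0 + \tfrac{d}{dt}\ln p_\mathrm{in}(t)\Big],$$

and for the LIF the bracket's intercept $-(K-1)h_0$ is replaced by $+h_0$,
which is the substitution that makes the zero-modulation current equal each
model's holding current.  The derivative
$\tfrac{d}{dt}\ln p_\mathrm{in} = -h_0 + \tfrac{d}{dt}\ln\Delta p_\mathrm{in}$
is evaluated analytically from the stored sinusoid parameters (a central
finite-difference fallback exists for tabulated modulations).  Because only
the derivative enters, normalization constants of the target never reach
the neuron.  The encoder requires the delta hazard kernel: the encoding
equation fixes the *filtered* current, and deconvolution for general
kernels is not attempted.

## The output log-modulation convention

`isi_transduction()` composes encoding, integration, hazard evaluation and
the renewal transform, and reads the output log-modulation directly off
the raw density:

$$\ln \Delta p_\mathrm{out}(t) = \ln p_\mathrm{out}(t) - \ln p_0(t),
\qquad p_\mathrm{out} = S\,h .$$

No window renormalization is applied.  This is a deliberate design choice:
the modulation of a renewal density is defined relative to its exponential
baseline, and renormalizing on a finite window would convert any *local*
trajectory error — notably an erroneous threshold crossing near
$V_0 \approx V_T$ at large $r_{\Delta p}$ — into a *global* offset of the
whole curve.  With renormalization in place the corner of the sweep plane
where the EIF occasionally escapes gets charged twice (once for the local
spike artifact, once for the induced offset), enough to make the LIF appear
better there, which contradicts both the analytic picture and the known
empirical ordering.  The raw convention keeps the damage local and the
EIF's dominance holds at every swept cell.

## Small-signal theory

Linearizing the hazard dynamics around the baseline gives the
probability-modulation transfer function

$$T(s) = \frac{s - h_0}{s - h_0 - K' h_0},\qquad
K'_{EIF} = -K c_0 + K - 1,\quad K'_{LIF} = -K c_0 - 1,\quad
c_0 = e^{(V_T - V_0)/\Delta_T},$$

evaluated on the imaginary axis $s = i 2\pi f$ for Bode curves
(`transfer_constants()`, `transfer_function()`, `bode()`; phase in degrees,
unwrapped, negative meaning lag; default frequency grid 200 log-spaced
points on 1–300 Hz).  High frequencies always pass undistorted
($T \to 1$); at low frequencies the feedback weight $|K'|$ matters, and
only the EIF's weight collapses to 1 as $V_0 \to V_T$, while the LIF's
grows to $K + 1$.

`predict_logmod()` applies $T$ per sinusoid.  Since the derivation assumes
zero initial conditions ($\Delta h(0) = \ln\Delta p(0) = 0$ — satisfied by
construction here because $V(0) = V_0$), the exact inverse Laplace
transform of $T(s)U(s)$ carries, besides the steady-state gain/phase
response, a start-up transient decaying at the system pole
$h_0(1 + K') < 0$; it is included by default (`transient = FALSE` recovers
the pure Bode reading).  A constant input component is not transduced at
all: nothing ever perturbs the hazard.  The simulation honors the same
anchoring, which is what makes the two directly comparable — the
cross-check in the test suite holds them to better than 10% relative
$L_2$ error at $r_{\Delta p} = 0.05$.

## Performance metric and sweeps

`l1_distance()` scores $\ln\Delta p_\mathrm{in}$ against
$\ln\Delta p_\mathrm{out}$ with the normalized $L_1$ distance
$\|f - g\|_1 / (\|f\|_1 + \|g\|_1) \in [0, 1]$.  The metric is scale
invariant, so two numerically null signals would be scored on roundoff
noise; a floor (combined norm below $10^{-8}$) therefore returns 0, which
also realizes the $r_{\Delta p} \to 0$ limit cleanly.

`run_sweep()` scans the $(V_0, r_{\Delta p})$ plane — by default 20
equidistant baselines from $-65$ mV to $V_T - 1$ mV and 20 ratios from
0.05 to 0.8, with a 5 × 5 `quick` grid used by the test suite for runtime
reasons.  One modulation seed is shared across the whole grid, so EIF/LIF
and neighbouring cells are compared on an identical phase realization
(regenerating phases per cell would add sampling noise to a comparison
that is about the models, not the targets).  The evaluation window is
0.5 s for *both* bands — five periods of the slowest modulation frequency
in use, and a common support for the matched-cell band comparison.  A
band-dependent window (five periods of each band's own lowest frequency,
i.e. 50 ms for the high band) was rejected: it leaves the high band
covering only a sliver of the ISI mass and makes matched cells
incommensurable.

## Range of realizable distributions

With $\ln\Delta p$ a stationary Gaussian process, $\Delta p(t)$ is
log-normal at every $t$; setting $\mu = -\sigma^2/2$ enforces
$\mathbb{E}[\Delta p] = 1$, and the fluctuation ratio reappears as the
coefficient of variation, $\sigma^2 = \ln(r_{\Delta p}^2 + 1)$
(`lognormal_params()`).  The per-time value distribution of
$p(t) = p_0(t)\Delta p(t)$ is then log-normal with log-mean
$\mu + \ln h_0 - h_0 t$ (`value_density()`), whose mean equals $p_0(t)$
exactly and whose quantile bands shrink like $e^{-h_0 t}$
(`range_summary()`, default quantiles 0.025, 0.25, 0.5, 0.75, 0.975).
Only this stationary marginal is modelled; no time-correlated process
realizations are constructed (doing so while keeping the implicit
normalization would require future information about the process).

## What the synthetic targets do and do not emulate

The generator produces band-limited, phase-randomized colored modulations
of an exponential ISI baseline — the stimulus family of the original
sweep experiments — under perfectly known parameters, which is what makes
oracle testing possible.  It does not emulate diffusive synaptic noise
(the hazard is its proxy), spike-frequency adaptation, non-renewal
history dependence, or measured cortical ISI data.  Passing tests
therefore certify the transduction theory and its implementation, not the
behaviour of biological neurons.

## Numerical choices, in one place

* Integration: cumulative trapezoid for all renewal integrals; RK3 for
  the membrane at $dt = 0.05$ ms.
* Spike detection at the first grid point at/above the criterion;
  integration continues under the clock-aligned current after reset.
* Survivor underflow below $10^{-300}$ clamps to zero and is flagged;
  hazard recovery refuses such windows naming the exhaustion time.
* $L_1$ null floor $10^{-8}$; ISI sampling requires 99% window mass.
* Non-delta hazard kernels are discretized at $dt$, renormalized to unit
  discrete integral, and convolved causally with a zero-padded past.
* Single-sinusoid specs place the frequency at `f_lo` (the equidistant
  formula is undefined for one component).
* Test-suite problem sizes: 0.5 s windows at $dt = 0.05$ ms
  (10,001-point grids), 5 × 5 quick sweeps, $10^6$-draw Monte-Carlo
  calibrations, 100 × 400 Kolmogorov–Smirnov calibration runs.

## Known limitations

The encoder is exact only in the small-signal regime; for
$r_{\Delta p} \gtrsim 0.6$ with $V_0$ within a millivolt of threshold the
deterministic EIF trajectory can erroneously reach the peak potential, and
the resulting reset leaves a genuine, mechanistic scar in the output
density (visible as a spike in $\ln\Delta p_\mathrm{out}$).  The LIF in
the same corner crosses its threshold far more often but each crossing is
gentler.  Both behaviours are physics, not artifacts, and both are kept.
The transfer theory ignores second-order terms in
$\Delta h / h_0$, which is why the simulation-versus-theory agreement is
held to 10% rather than machine precision even for weak modulation.
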
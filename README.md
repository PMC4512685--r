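# isisampler

Interspike-interval (ISI) random sampling with exponential and leaky
integrate-and-fire neurons (EIF / LIF) in the high-conductance, UP-state
regime.

## The problem

During slow-wave sleep and anesthesia, cortical neurons alternate between a
depolarized, high-conductance UP state near firing threshold and a
hyperpolarized DOWN state.  One quantitative interpretation of the UP state
is that the neuron acts as a random sampler: every spike carries, as an
analog value, the ISI that preceded it, so a spike train is a stream of
draws from an ISI distribution `p(t)`.  A presynaptic population can select
that distribution by shaping the input current, and the neuron becomes a
*probability transducer*.

`isisampler` is for computational neuroscientists who want to simulate and
analyze this transduction.  The target distribution is a multiplicatively
modulated exponential,

```
p_in(t) = p0(t) * Dp_in(t),     p0(t) = h0 * exp(-h0 * t),
```

encoded as a current that is linear in `d/dt ln p_in(t)`.  The membrane
equation (EIF, with the LIF as the `Delta_T -> 0` limit)

```
dV/dt = -(V - E_L)/tau_m + (Delta_T/tau_m) * exp((V - V_T)/Delta_T) + I*(t)
```

is integrated deterministically (3rd-order Runge–Kutta), and firing is
governed by the escape-noise hazard

```
h(t) = 1/(K * tau_m) * exp((V(t) - V_T)/Delta_T),
```

calibrated to 10 Hz at threshold.  The renewal relations `S = exp(-∫h)`,
`p = S·h` recover the output ISI distribution, and the match to the target
is scored with the normalized L1 distance of the log-modulations.  The
small-signal probability-modulation transfer function

```
T(s) = (s - h0) / (s - h0 - K' * h0),      s = i·2πf,
K'_EIF = -K·c0 + K - 1,   K'_LIF = -K·c0 - 1,   c0 = exp((V_T - V0)/Delta_T)
```

explains analytically why the EIF — and only the EIF — transduces
low-frequency modulations faithfully as the baseline voltage `V0`
approaches threshold: `|K'_EIF| -> 1` while `|K'_LIF| -> K + 1`.

## Worked example

The broadband showcase: 60 random-phase sinusoids on [10, 200] Hz,
fluctuation ratio 0.44, baseline one millivolt below threshold.

```r
library(isisampler)
np <- neuron_params("high")      # UP-state parameter set, tau_m ~ 1.9 ms
hp <- hazard_params(np)          # K ~ 53.4, 10 Hz at threshold
grid <- time_grid(dt = 5e-5, t_max = 0.5)
target <- build_target(modulation_spec(60, 10, 200, r_dp = 0.44, seed = 1),
                       V0 = -51.4, np, hp, grid)
fit_eif <- isi_transduction(target, np, hp, model = "eif")
fit_lif <- isi_transduction(target, np, hp, model = "lif")
fit_eif
#> ISI transduction (EIF, high conductance)
#>   V0 = -51.4 mV, h0 = 7.165 Hz, r_dp = 0.44
#>   normalized L1(ln Dp_in, ln Dp_out) = 0.2862
fit_lif
#> ISI transduction (LIF, high conductance)
#>   V0 = -51.4 mV, h0 = 7.165 Hz, r_dp = 0.44
#>   normalized L1(ln Dp_in, ln Dp_out) = 0.5615
```

The baseline hazard at `V0 = -51.4 mV` is 7.2 Hz, and the EIF halves the
LIF's approximation error on the same target.  `summary()` additionally
reports the voltage excursion (1.84 mV here, safely below the 3 mV slope
factor) and any erroneous threshold crossings; `plot(fit_eif)` draws the
log-modulations and densities; `simulate(fit_eif, 1000)` draws ISIs from
the fitted output distribution.

In the weak-modulation regime the simulation agrees with the analytic
transfer prediction:

```r
weak <- build_target(modulation_spec(1, 50, 50, r_dp = 0.05, seed = 2),
                     V0 = np$V_T - 1, np, hp, grid)
fit <- isi_transduction(weak, np, hp, "eif")
pred <- predict(fit)    # closed-form small-signal prediction
sqrt(sum((fit$ln_dp_out$values - pred$values)^2) / sum(pred$values^2))
#> [1] 0.083
```

And the Bode tables make the EIF/LIF asymmetry explicit — at a deep
baseline (-65 mV) the two models are indistinguishable, while near
threshold only the EIF's gain climbs toward 1:

```r
bode(frequencies = c(5, 50), V0_values = c(-65, -51.4),
     neuron = np, hazard = hp)
#>   frequency_hz model V0_mV  gain phase_deg
#> 1            5   eif -65.0 0.059      86.7
#> 2           50   eif -65.0 0.510      59.3
#> 3            5   lif -65.0 0.059      86.8
#> 4           50   lif -65.0 0.507      59.5
#> 5            5   eif -51.4 0.209      91.1
#> 6           50   eif -51.4 0.901      27.0
#> 7            5   lif -51.4 0.060      99.5
#> 8           50   lif -51.4 0.507      60.8
```

Higher-level experiment runners (`run_simulation_experiment()`,
`run_bode_experiment()`, `run_sweep_experiment()`,
`run_range_experiment()`) write CSV tables plus a `manifest.json` that
reproduces the run bit-identically; `inst/cli/isisampler.R` wraps them as
the shell commands `simulate`, `bode`, `sweep` and `range`.

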
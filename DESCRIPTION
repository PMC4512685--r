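Package: isisampler
Title: Interspike-Interval Random Sampling with Exponential
    Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates exponential and leaky integrate-and-fire (EIF/LIF)
    neurons used as interspike-interval (ISI) random samplers in the
    high-conductance (UP-state) regime.  A user-defined ISI distribution,
    built as a multiplicative modulation of an exponential baseline, is
    encoded as an input current; the deterministic membrane trajectory is
    integrated with a third-order Runge-Kutta scheme and converted to an
    output ISI distribution through a voltage-dependent escape-noise
    hazard.  The package provides renewal-theory transforms between
    hazard, survivor function and ISI density, inverse-transform ISI
    sampling, small-signal probability-modulation transfer functions with
    Bode analysis, normalized L1 performance sweeps over baseline voltage
    and modulation depth, and an analytic log-normal estimate of the
    range of realizable ISI distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
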
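---
title: "Mapping LIF neurons onto fixed-point compartments: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping LIF neurons onto fixed-point compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifbridge)
```

## The two models and the bridge between them

A leaky integrate-and-fire (LIF) point neuron in physical units obeys

$$ V'(t) = \frac{1}{C}\Big[I_e(t) - \frac{1}{R}\big(V(t) - E_L\big)\Big],
\qquad V(t) \leftarrow V_r \ \text{ if } V(t) > \Theta, $$

with membrane time constant $\tau_v = RC$ (ms), capacitance $C$ (pF),
resting potential $E_L$, reset $V_r$, threshold $\Theta$ (mV) and bias
current $I_e$ (pA). Digital neuromorphic compartments implement a
discrete-time, unit-less analogue with two fixed-point state registers,
a synaptic current $u$ and a membrane potential $v$:

$$ v(t+1) = v(t)\Big[1 - \frac{\delta_v}{2^{12}}\Big] + b + u(t),
\qquad v \leftarrow 0 \ \text{ if } v > \theta, $$

with $\pm$23-bit states, a 12-bit decay word $\delta_v$, a threshold
stored in the 17 high bits of a 23-bit word (granularity $2^6$), and the
constant drive encoded as $b = \text{mant} \cdot 2^{\text{exp}}$ with
mantissa in $[-2^{12}, 2^{12}]$ and exponent in $[0, 7]$.

The bridge is an affine state rescaling plus a time discretization:

$$ v = \frac{V - V_r}{V_s}, \qquad t \mapsto t/dt, $$

so the reset maps to the fixed-point origin. Matching the hardware update
to a forward-Euler discretization of the rescaled dynamics yields the
parameter map implemented in `loihi_compartment()`:

* $\delta_v = (dt/\tau_v)\,2^{12}$, rounded to an integer in $[1, 4096]$
  (`compute_voltage_decay()`);
* $\theta = (\Theta - V_r)/V_s$, quantized to multiples of $2^6$
  (`map_threshold()`);
* $b^* = dt\,[I_e/C + (E_L - V_r)/\tau_v]/V_s$ levels per step, encoded
  with the smallest exponent whose mantissa fits (`map_bias()`). The
  constant part of the drive --- injected current *and* the leak offset
  when $E_L \neq V_r$ --- is folded entirely into $b$; only spike-driven
  synaptic input flows through $u$. This follows from the hardware update
  rule keeping $b$ separate from $u$ while the continuous drive term
  contains both.

The package's two sides are `simulate_reference()` (continuous model,
exact integration) and `simulate_emulator()` (bit-faithful fixed-point
update); `compare_runs()` inverse-maps the emulator trace via
$V = v V_s + V_r$ and scores the pair.

## Reference numerics: exact integration

Subthreshold, the continuous system (exponential synaptic current feeding
a leaky membrane with constant drive) is linear, so it is advanced by one
matrix multiplication per step with the closed-form matrix exponential
over the state $(I_{\text{syn}}, V, 1)$ (`build_propagator()`). There is
no truncation error: grid samples equal the analytic solution, which the
test suite verifies against an independent fixed-step Runge--Kutta
integration at $h = 10^{-3}$ ms (agreement within $10^{-6}$ mV over
500 ms) and against grid refinement (samples unchanged to $10^{-9}$ mV).
The degenerate case $\tau_{\text{syn}} = \tau_v$ uses the analytic limit
of the coupling term, $(h/C)e^{-h/\tau}$.

Threshold crossings are detected at grid points only, with the strict
test $V > \Theta$, and reset precedes recording. This mirrors the
discrete backend, keeping the two sides comparable; it means recorded
spike times can shift by one grid step relative to the continuous
crossing. There is no refractory period in either model.

## Emulator numerics

The fixed-point update truncates with `floor` after each decay multiply
(arithmetic-shift semantics of a hardware register), saturates both
states at $\pm(2^{23}-1)$ instead of wrapping (with a diagnostics
counter), and applies the threshold test after the current term is added
(`threshold_before_u` exposes the alternative ordering, which is not
derivable from the hardware description). Within a step the order is:
decay $u$, add spike input, decay $v$, add $b$ and $u$, test, reset.
Per step the truncation error is below one level in $u$ and two levels
in $v$, which the suite checks against a real-valued step on random
states, alongside an exact equivalence check against an independently
written integer oracle on $10^5$ random states.

## Choices where the hardware description is silent

**Rounding.** All quantization points round to nearest, ties away from
zero; `mapping_config(rounding = "floor")` switches to truncation for
sensitivity checks.

**Voltage vs. current decay words.** The voltage decay word follows the
published linear correspondence $\delta_v = (dt/\tau_v)2^{12}$ --- this is
the documented hardware contract, and we keep it even though an
exponentially matched word would track the continuous decay more closely.
No analogous formula is documented for the current decay word, so there
the package is free to choose, and it calibrates exponentially:
$\delta_u = \mathrm{round}\big(2^{12}(1 - e^{-dt/\tau_{\text{syn}}})\big)$,
making the per-step multiplier match the exponential kernel to 12-bit
precision. The distinction matters because typical synaptic time
constants are comparable to the step: at $\tau_{\text{syn}} = 2$ ms and
$dt = 1$ ms the linear word gives a per-step factor of $0.5$ against the
true $e^{-0.5} \approx 0.607$, visibly distorting every postsynaptic
potential and capping the achievable trace correlation near $0.9974$,
whereas the calibrated word keeps spike-driven fidelity at the same
$r > 0.9999$ level as the bias-driven path. For the membrane potential
($\tau_v \gg dt$) the linear word's error is two orders of magnitude
smaller, which is why the published linear contract is unproblematic
there.

**Synaptic kernel and weight.** External spikes deliver an instantaneous
jump of the weight (pA) onto the synaptic current, which decays with
$\tau_{\text{syn}}$ (default 2 ms, an ordinary fast-excitatory value).
The packaged five-source spike table carries no printed weight; the
default 100 pA produces ~2 mV peak deflections, and the fidelity
correlation is insensitive to this choice (it rescales both sides).

**Defaults $V_s = 10^{-4}$ mV/level and $dt = 1$ ms/step.** The
voltage-precision sweep shows membrane error saturating from
$10^{-3}$ to $10^{-4}$ mV/level, and the temporal sweep shows raw error
minimized at 1 ms; both defaults sit at those optima. Finer $V_s$ costs
nothing except threshold-overflow risk (the threshold must stay below
$2^{23}$ levels, which `map_threshold()` enforces); finer $dt$ multiplies
the step count and shrinks the representable time-constant range
$\tau_v \in [dt, 2^{12}dt]$ (about 41 ms at $dt = 0.01$ ms, enforced by
`compute_voltage_decay()`).

## What the fidelity experiments measure

The single-neuron experiments record **subthreshold** dynamics
(`threshold = FALSE` on both backends). This is deliberate: the
fixed-point side is a forward-Euler scheme whose mapped firing period
differs from the exact-integration period by about one step in sixty for
the packaged bias-driven model, so thresholded traces slowly desynchronize
and the correlation collapses to ~0.62 for reasons that have nothing to
do with state fidelity --- the quantity under study. Subthreshold, the
same pair correlates at $r = 0.99994$. Spike-time agreement is covered
separately (first-spike step within the discretization bound of the
analytic crossing).

Run-level errors are reported on two scales: the per-sample RMSE in mV,
and `rmse_per_ms`, the per-sample RMSE divided by the number of 1-ms-grid
samples of the run. The packaged 500-ms experiments quote the latter
(units mV/ms); at the default step the two differ by exactly the factor
500. The report stores both, so either convention is recoverable.

The precision sweeps use two stimulus configurations because the two
findings live on different states: the membrane-potential inequality
(coarser $V_s$ inflates error) is asserted under bias drive, where
voltage quantization dominates; under spike drive the membrane error is
floored by the $V_s$-independent Euler coupling error (~0.2 mV) and the
inequality is not reliable. The current-state flatness between
$V_s = 10^{-4}$ and $10^{-5}$ requires spike drive (otherwise $u \equiv 0$).
That flatness itself reflects the cross-platform sampling convention:
both sides record end-of-step registers, and at an arrival step the
discrete register holds the undecayed arrival while the continuous state
has already decayed it --- a floor independent of $V_s$.

## Stimuli and networks

`poisson_sources()` draws homogeneous Poisson trains (counts Poisson,
arrival times uniform given the count), frozen by seed, truncated at the
window; the suite checks the mean count calibration (2.5 spikes per
source at 5 Hz over 500 ms) and the exponential inter-spike-interval law
by a Kolmogorov--Smirnov test. The packaged five-source table is one such
frozen draw.

`build_random_network()` wires every ordered pair of distinct neurons
independently with probability `p_conn` (no self-connections), splits the
population into excitatory and inhibitory classes (weights $\geq 0$ and
$\leq 0$ respectively, set by the presynaptic class), and maps every
neuron through the parameter pipeline. `simulate_network()` is
event-driven with a fixed one-step synaptic delay on both backends; the
suite checks permutation equivariance of the spike table, lockstep firing
of unconnected identical neurons, the hand-traced one-step delivery
delay, binomial edge counts, and per-neuron cross-backend correlation
above 0.999 on a quiet random network. `sample_ensemble_params()`
synthesizes multi-class parameter collections over physiological ranges
(time constant 10--40 ms, capacitance 80--300 pF, bias 0--250 pA) for
ensemble-structure experiments; it is a synthetic stand-in, not a curated
cell-type catalogue.

What the synthetic conditions do not emulate: measured cell-type
parameter correlations, inhomogeneous firing rates, synaptic delays
beyond one step, refractoriness, and any learning dynamics. Passing
tests therefore certify the mapping and the numerics, not biological
realism of the stimuli.

## Problem sizes

The packaged experiments are sized to the paper-scale studies they
mirror: 500 ms single-neuron runs (500 steps at the default grid; 5,000
at $dt = 0.1$), networks of tens to hundreds of neurons for structural
checks, $10^5$ random states for the integer-step equivalence, and 4,000
Poisson sources for the rate calibration.

## Known limitations

* The voltage-decay word follows the linear published contract, so the
  emulator's effective membrane time constant differs from $\tau_v$ by
  $O(dt/\tau_v)$; tonic firing rates consequently differ by about one
  grid step per period from the exact reference. Calibrating $\delta_v$
  exponentially (as done for $\delta_u$) would remove most of this but
  would no longer model the documented hardware.
* Axonal delays (hardware range 1--62 steps) are validated as a range but
  fixed at one step in simulation; weight-exponent encodings of the
  physical synapse memory are not modelled beyond the integer-increment
  contract.
* Network-level cost functions (rate/correlation comparisons) are out of
  scope; cross-backend network checks are per-neuron trace statistics.
* Run containers are plain-text directory layouts with hashed manifests;
  no binary container format is produced.
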
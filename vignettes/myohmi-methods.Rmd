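---
title: "Models and methods behind the myohmi pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the myohmi pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myohmi)
```

This vignette explains the models implemented by the package, the choices
made where the design was genuinely open, and what the synthetic benchmark
does and does not demonstrate about real recordings.

## The interface being simulated

A single bipolar surface-EMG channel on the biceps brachii drives a
three-degree-of-freedom virtual arm. The user's vocabulary is the duration
of an isometric contraction: a sharp ~1 s pulse (SMP), a 3 s pulse (SMP3) or
a 5 s pulse (SMP5), always followed by a 5 s rest pause; rest and
involuntary movements form a fourth class (NIM) that acts as a safety stop.
Classified events drive a Mealy machine whose states carry Cartesian
set-points; inverse kinematics converts each set-point to joint angles and a
PD+ controller drives the simulated arm there.

## Synthetic sEMG generator

Surface EMG during an isometric contraction is well approximated, for
signal-processing purposes, by amplitude-modulated band-limited Gaussian
noise. The generator uses exactly that surrogate:

* **Carrier**: white Gaussian noise passed twice through a Butterworth
  band-pass designed at 20–450 Hz (the cascade squares the magnitude
  response, so the −3 dB design edges become −6 dB and at least 95% of burst
  power stays inside the stated band), normalized to unit RMS and hard
  limited at ±3 standard deviations.
* **Envelope**: a trapezoid with 100 ms rise and fall ramps at the planned
  contraction duration, jittered by ±15% so that class durations overlap
  slightly and classification is not trivially separable on duration alone.
  The envelope value is `A/3` during a burst of amplitude bound `A` (so
  samples never exceed `A`) and 0.05 mV RMS at rest.
* **NIM windows**: two to four erratic sub-bursts of 0.3–1.5 s at 10–40% of
  the voluntary amplitude, plus sinusoidal baseline wander below 0.5 Hz
  (amplitude 0.05 mV), emulating involuntary jerks and electrode drift.
* **Interference**: an optional sinusoidal mains component and DC offset can
  be added afterwards (`emg_inject_interference()`).

Amplitudes are restricted to the physiological 0.1–5 mV range and the
default sampling rate is 10 kHz, matching the acquisition hardware being
emulated. All randomness flows from one seed; equal seeds give bit-identical
sessions.

What the surrogate does **not** model: motor-unit action potentials and
recruitment, electrode–skin impedance, amplitude non-stationarity within a
contraction, fatigue, or crosstalk from neighboring muscles. Consequently a
perfect benchmark score here demonstrates the correctness of the pipeline's
machinery, not clinical-grade performance on human data.

## The digital filter and its tuning

The low-pass stage is the first-order discretization of an RC filter. With
sampling period `T` and cutoff `f_c`, the difference equation is

    v_o[n] = a v_o[n−1] + (1 − a) v_in[n−1],   a = exp(−2π f_c T).

The one-sample input delay is part of the printed recursion and is kept
exactly; the first output sample equals the `initial_output` argument
(default 0). The closed-form magnitude response `|1 − a| / |e^{jωT} − a|`
(`lowpass_gain()`) has unit DC gain for every valid `f_c`, and the filter is
stable because `0 < a < 1` whenever `0 < f_c <` Nyquist.

Spectra are plain rectangular-window DFTs (an optional Hann window exists
for exploratory use); per-bin energies fold the negative frequencies onto
`[0, Nyquist]` so that Parseval's identity holds to machine precision.
The tuning rule: the dominant non-DC bin is taken as the interference
frequency; if it lies above the 450 Hz band edge the cutoff is placed at the
geometric mean of edge and interference (log-midway between passband and
stopband — the natural compromise for a 20 dB/decade one-pole roll-off); if
the interference falls inside the signal band a low-pass cannot remove it,
so the cutoff stays at the band edge and a warning is emitted. Exact ties
between bins resolve to the lower frequency.

## Segmentation, features and the classifier

Bursts are detected on a 100 ms moving-RMS envelope crossing three times the
rest RMS, estimated as the median envelope (robust because the protocol
rests at least half the time). Detections closer than 0.5 s merge; those
shorter than 0.3 s are kept as candidate involuntary events; rest stretches
of 2 s or more are emitted as NIM segments for labeling and reporting.

Each segment is summarized by four features — duration, RMS, mean absolute
value and zero-crossing rate. Duration is the class-defining quantity of the
protocol; RMS/MAV separate voluntary effort from involuntary noise; ZCR
summarizes spectral content. Features are standardized to zero mean and unit
*population* standard deviation with a scaler fitted on the training table.

The classifier is a 4-4-4 multilayer perceptron: ReLU hidden layer, softmax
output, one-hot targets (NIM = 0, SMP = 1, SMP3 = 2, SMP5 = 3), categorical
cross-entropy in its conventional negated-mean form, full-batch Adam
(learning rate 0.01, β₁ = 0.9, β₂ = 0.999, ε = 1e−8, bias-corrected
moments), weights initialized uniformly in `[−0.5, 0.5)`, 3000 epochs, a
0.20 test split and 0.1 validation split drawn with seed 42. Back-propagated
gradients are verified against central finite differences in the test suite.
Arg-max ties resolve to the lowest class index.

Two labeling regimes exist, and they matter:

* the **protocol benchmark** labels ground-truth intervals directly (as the
  acquisition protocol does) — this is the configuration behind the
  held-out-accuracy figure;
* **deployment** classifies whatever the detector finds, so deployment
  models should be trained on detector output labeled by ground-truth
  overlap (`label_segments()`), keeping both distributions identical.

A known limitation follows from the feature set: a single large involuntary
jerk of ~1 s is genuinely ambiguous with a weak sharp pulse (same duration,
overlapping RMS), so deployment accuracy is below the protocol benchmark.
The confusion that remains concentrates between adjacent-duration classes.

## The command machine

The machine has eight motion states (Stop, Up, Right, Left, the four
diagonals) plus a deactivated HOME. Inputs are one-hot 4-bit words in the
order [NIM, SMP3, SMP5, SMP] from most to least significant. From any motion
state: SMP returns to Stop; SMP3 toggles the vertical component (a second
SMP3 from an up-diagonal reaches the corresponding down-diagonal); SMP5
cycles the horizontal component. NIM moves to HOME and deactivates the
machine — a safety response — and only an explicit reset reactivates it. The
full transition table ships as a versioned JSON asset
(`inst/extdata/transition_table.json`); the emitted set-point of each state
is fixed in `state_targets()`. Long rest pauses are part of the protocol and
do not drive the machine; only detected activity events do.

## Robot model and control

**Kinematics.** The arm is a 3R anthropomorphic chain: base rotation about
the vertical axis, shoulder and elbow in the vertical plane. The forward map
uses the full link lengths `l2`, `l3` so that the closed-form inverse (base
angle by `atan2`, shoulder by the tangent half-angle solution of
`a cos q2 + b sin q2 = c` with `c = r² + u² + l2² − l3²`, elbow from the
planar residuals) is an exact inverse — the round-trip residual is at
numerical precision on all command set-points and a thousand random
reachable points. Points on the base axis leave the base angle undefined;
it is resolved to 0 with a warning.

**Dynamics.** The lumped model places point masses at the link centers of
mass with scalar link inertias. The inertia matrix is derived from the
kinetic energy (its `M22`, `M23`, `M33` entries coincide with the standard
printed forms for this chain; the base row couples only through its own
configuration-dependent term, which guarantees symmetric positive
definiteness for all configurations). The Coriolis matrix comes from the
Christoffel symbols of `M`, which enforces the skew-symmetry of `Ṁ − 2C`;
gravity is the exact gradient of the potential energy; viscous friction is
diagonal.

**Parameters and gains** are not dictated by the interface design, so the
package fixes a desk-scale default: `l1 = 0.30 m`, `l2 = l3 = 0.25 m`
(chosen so every command set-point is strictly inside the workspace),
`lc_i = l_i/2`, masses (1.0, 1.0, 0.8) kg, link inertias 0.01 kg·m²,
friction 0.1 N·m·s/rad, g = 9.81 m/s², `K_p = diag(100)`, `K_v = diag(20)`
(N·m/rad and N·m·s/rad). The gains give a heavily damped closed loop whose
slowest pole ≈ `K_p/K_v = 5 s⁻¹`, settling far below a milliradian within
the 5 s command window.

**Control and integration.** The PD+ law adds full model feedforward to PD
feedback; for the set-point case the feedforward vanishes and the law is PD
plus exact gravity compensation, whose unique closed-loop equilibrium is the
target itself. Integration is fixed-step RK4 at 1 ms (2 ms ceiling); halving
the step moves the final state by less than 1e−6 rad. A passive arm with
gravity, friction and torque removed conserves kinetic energy to ~1e−14
relative over 5 s, which bounds the integrator's energy error well under the
1e−6 target used in the tests. Simulations abort with a diagnostic if joint
speed exceeds 1000 rad/s.

## Evaluation harness

Trajectory tasks are ordered waypoint lists over machine states. Every
visited state that is not the next expected waypoint counts one penalty; a
trial completes when the last waypoint is reached. Response time is the EMG
timeline length of the scripted session — burst plus rest durations — so
results are hardware independent. The learning-curve summary is
`100 (t_first − t_last) / t_first` reported at two decimals. For the
reference response-time pairs (118.52, 77.54) and (188.64, 111.99) seconds
this gives 34.58% and 40.63% (the second figure is commonly quoted as
40.64%, a rounding difference in its source).

## Problem sizes and numerical choices

The full benchmark — 160 bursts at 10 kHz (~23 min of signal, 13.6 M
samples), 3000 training epochs, eight 5 s regulation runs at 1 ms steps —
was chosen to mirror the acquisition protocol while completing in about two
minutes on one CPU; the unit suite uses reduced rates (2 kHz) and epoch
counts for speed. Degenerate inputs fail loudly everywhere: empty plans,
non-positive amplitudes or durations, mixed sample rates, constant feature
columns, out-of-range labels, non-positive-definite gains, unreachable
targets and diverging simulations all raise informative errors rather than
propagating silently.
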
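---
title: "Validation methods: protocols, scoring rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation methods: protocols, scoring rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoval)
```

`hippoval` scores single-neuron models of hippocampal CA1 pyramidal
cells against experimental electrophysiology. This vignette documents
the science behind the package: the scoring model, each test's protocol
and its assumptions, the parameters that matter, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## The scoring model

Every test reduces to the same statistical comparison. A feature
extracted from the model's voltage response, $x$, is compared with the
experimental mean $\mu$ and standard deviation $\sigma$ of the same
feature measured across cells:

$$Z = \frac{|x - \mu|}{\sigma}.$$

$Z$ is dimensionless and expresses the model–experiment discrepancy in
units of biological variability; the final score of a test is the mean
of the $Z$ values of its evaluated features (plus test-specific
penalties described below). Two consequences worth keeping in mind:

* a score of 0 means the model reproduces every feature mean exactly,
  not that the model is "correct" — the observation's $\sigma$ bounds
  the resolution of the comparison;
* scores are comparable across features but not across observation
  files with different variability.

Features that cannot be evaluated — spiking features of a trace without
spikes, vector features empty after the exclusion rule, distance ranges
without recording sites — carry no numeric sentinel at all. They are
excluded from aggregation by construction, counted in
`n_attempted`, and listed in the log file. This is deliberate: a
sentinel value (0 or a large constant) would silently bias the mean.

## Feature extraction

The extraction registry (`feature_registry()`) documents the exact
formula and windowing of every supported feature; names follow the
eFEL-compatible vocabulary so existing observation files work
unchanged. Conventions:

* **Spike detection** is an upward crossing of a threshold, default
  −20 mV everywhere (one knob, overridable per test). The AP begin
  point is found on the rising phase by a derivative criterion:
  the first sample of the maximal contiguous run of slopes
  ≥ 10 V/s ending at the crossing, requiring at least 3 samples of
  sustained rise. A derivative criterion is the community convention;
  the exact constants are configurable arguments of `detect_spikes()`.
* **Vector features** (one value per AP) are averaged. For features
  derived from the AP begin point (`AP_begin_voltage`, `AP_width`,
  rise/fall features, ...) the first element is dropped before
  averaging, because the begin point of the first AP of a train is
  frequently mis-detected near stimulus onset; a vector that becomes
  empty after exclusion makes the feature unevaluable.
* **Window statistics are time-weighted** (trapezoid quadrature with
  interpolated window edges), so variable-step traces are handled
  identically to fixed-step ones. `voltage_base` averages over
  [0.9·delay, delay]; `steady_state_voltage_stimend` over the last 10%
  of the stimulus. Both windows mirror common library defaults and are
  part of the registry documentation rather than hidden constants.

## The five tests

### Somatic features

Step currents of the amplitudes named in the observation file are
injected at the soma; every observed feature is extracted at every
amplitude and Z-scored. One design question was whether a feature
evaluated at several amplitudes contributes one pooled score or one
score per amplitude; we score **per amplitude** (feature keys like
`AP_amplitude@0.15`) and average at the end, which keeps the
amplitude-resolved discrepancies visible in the result file.

### Depolarization block

1000 ms steps from 0 to 1.6 nA in 0.05 nA increments. Three features:

* `I_maxNumAP` — the amplitude with the maximal spike count. Ties are
  resolved to the **lowest** such amplitude, which keeps the feature
  deterministic and matches the experimental reading of the threshold
  current as the last amplitude before the count drops.
* `I_below_depol_block` — one step below the lowest amplitude at which
  the model fires no AP during the last 100 ms of the stimulus (block
  is only diagnosed above `I_maxNumAP`).
* `V_eq` — the time-weighted mean over the last 100 ms, taken one step
  above `I_maxNumAP` and iterated upward past traces that still spike
  late, i.e. at the first genuinely blocking trace.

If the two current features differ, a penalty of 10 per examined step
is added; we compute it as `10 * round(|ΔI|/step)` rather than
`200·|ΔI|` so that the result is exact in floating point (the two are
algebraically identical at step 0.05 nA). A model that never blocks
scores a flat 100 — a deliberate discontinuity marking a qualitative
failure rather than a graded discrepancy.

The block criterion ("no AP in the last 100 ms") is deliberately
behavioral, and a model can satisfy it without its membrane settling at
a depolarized equilibrium — e.g. when AP amplitudes shrink below the
detection threshold while the membrane keeps oscillating. The mock
family reproduces this "cheating" regime (`block$cheat = TRUE`) so the
limitation is visible in tests rather than hidden.

### Back-propagating AP

The amplitude search scans 0–1.0 nA in 0.1 nA steps, requires a firing
rate in 10–20 Hz, prefers the rate nearest 15 Hz, errors out on
spontaneous spiking or rates that never reach 10 Hz, and falls back to
binary search when the rate jumps over the band between consecutive
steps. Firing rate is measured as spike count over the 1 s stimulus.

bAP amplitudes use the test's own extraction rule rather than spike
detection on the dendritic trace, because distal back-propagating
signals may never cross a fixed threshold: the somatic AP begin times
define the measurement windows, and the amplitude is the dendritic
maximum within the window minus the dendritic voltage 1 ms before the
somatic begin (early enough to miss the rising phase, late enough to
avoid the previous AP's afterhyperpolarization). Amplitudes are
averaged within 50/150/250/350 ± 20 µm path-distance ranges; empty
ranges (coarsely segmented proximal sections can have no segment within
50 ± 20 µm) are skipped with a note.

Where the observation distinguishes strongly and weakly propagating
cells, the model is classified by the smaller |Z| of its first-AP
amplitude at the most distal evaluable range against the two targets,
and the class-specific features are scored against the chosen class;
class-independent features are scored as-is. Whether classification
should feed back into proximal ranges is not settled; scoring all
class-variant features against the single chosen class is this
package's choice, recorded here rather than asserted as the only
defensible one.

### PSP attenuation

Input locations are drawn at random from the trunk because the
evaluated ranges (100/200/300 ± 50 µm) cover nearly its whole length;
the probability of a segment is proportional to its length, duplicates
and out-of-bounds draws are rejected and redrawn, and if more locations
are requested than eligible segments exist, all segments are used. The
draw is governed by a single seed recorded in the result, making the
selection reproducible.

At each location a zero-weight baseline run yields the resting
potential $V_m$ (time-weighted mean of the final 10% of the trace), and
the synaptic weight reproducing the target EPSC amplitude follows from
assuming a 0 mV synaptic reversal:

$$w = -\mathrm{EPSC}_\mathrm{amp} / V_m .$$

Baseline traces are subtracted from stimulated ones before taking
peaks, so slow drift cancels; attenuation is the somatic peak
depolarization over the dendritic one.

### Oblique integration

Eligible dendrites are terminal obliques whose origin lies within
120 µm path distance of the soma; if none qualifies the limit grows in
15 µm steps to at most 190 µm. Each dendrite is probed at a proximal
and a distal location (arc positions 0.3 and 0.7 of the section — the
protocol says "a proximal and a distal location" without fixing
coordinates; these are this package's defaults, configurable).

The synaptic weight at each location is calibrated by bisection so that
the **first dendritic spike occurs at exactly 5 synchronous inputs**
(0.1 ms apart), with the postcondition verified by re-simulation at 4
and 5 inputs after the bracket collapses below `c_step_stop`. Locations
where the threshold spike also fires a somatic AP, or where no
dendritic spike is achievable at the top of the weight interval, are
excluded and listed — recorded, not repaired, mirroring how calibration
failures behave on real models. When the bracket collapses without
satisfying the postcondition (non-monotone responses), the location is
likewise excluded with a note.

Nine features are computed per location and averaged. The degrees of
nonlinearity need a linearity baseline that the protocol names but does
not formalize; we define the **linear prediction** for $n$ inputs at
interval $\Delta$ as the peak of the unitary somatic depolarization
shifted by $k\Delta$, $k = 0..n-1$, and summed. Nonlinearity is then
100 × measured peak / linear prediction, evaluated at the threshold
count (at threshold), one input above it (suprathreshold), and under
2 ms asynchronous inputs (asynchronous). This definition makes a
perfectly linear dendrite read 100% in both regimes by construction.
The voltage threshold for dendritic spike initiation is the linear-sum
somatic depolarization at the first spiking input count — a direct
transcription of "expected somatic depolarization" at the spike
threshold using spike detection as the change-point criterion (a
dV/dt-jump detector would be an alternative; spike detection keeps the
criterion identical to the one used during calibration).

The default synapse is a double-exponential AMPA conductance
(τ₁ = 0.1 ms, τ₂ = 2.0 ms) with an NMDA component using Jahr–Stevens
magnesium-block voltage dependence and rise/decay time constants of 3.3
and 102.38 ms; the AMPA/NMDA peak-conductance ratio defaults to 2.0.
The NMDA constants are stored already temperature-corrected; the Q10
factors (2.2 rise, 1.7 decay) are carried for provenance and never
re-applied. The Jahr–Stevens constants
$1/(1 + ([\mathrm{Mg}]/3.57\,\mathrm{mM})\,e^{-0.062 V})$ are the
canonical published values, stored as parameters rather than baked in.

## Morphology

Path distance — used consistently throughout the suite — is measured
from the soma root node along the 3D polyline; the soma's spatial
extent is ignored (all soma nodes sit at distance 0). Sections are
maximal unbranched chains of same-type nodes; for location selection a
section is discretized into geometric segments of at most 10 µm
(configurable), decoupling "segment" from any simulator's
discretization.

The apical point is where the trunk ends and the tuft begins. The
search starts from the tuft endpoints — operationalized as apical
terminals whose path distance is at least a fraction (default 0.6) of
the most distal terminal's, so oblique side-branch terminals do not
seed it — and takes their common ancestor. If that ancestor is closer
to the soma than a threshold (default 100 µm: far enough to reject
proximal trunk bifurcations, well below genuine CA1 apical points), the
search recurses into its child subtrees, yielding multiple apical
points for morphologies whose trunk splits near the soma. The threshold
compares **path** distance; the alternative (Euclidean) is not used
anywhere else in the suite. Trunk sections lie on the root paths of
apical points, tuft sections are distal to them, the remaining apical
sections are obliques. Degenerate arbors without any bifurcation take
the most distal node as the apical point rather than failing.

## The mock backend: what it emulates and what it does not

`mock_model()` renders voltage traces in closed form — no differential
equations — as a pure function of (parameters, protocol). It emulates,
with controllable ground truth: a linear f–I curve above rheobase with
amplitude-dependent first-spike latency; stereotyped triangular AP
waveforms; a sag overshoot whose steady/peak ratio is
≈ 1/(1+`sag_fraction`); depolarization block (silencing at `t_block`,
settling at `v_eq`, at most `max_spikes` APs) and its "cheating"
variant; distance-dependent bAP amplitudes
`plateau + (A0 − plateau)·exp(−d/λ)`; exponential dendro-somatic EPSP
transfer `coupling·exp(−d/λ_PSP)`; and an all-or-none dendritic spike
fired iff inputs are synchronous and `count·weight` crosses a fixed
threshold, with only a fraction of its amplitude coupled to the soma.

It does **not** emulate: conductance interactions, AP shape changes
with rate, adaptation, stochastic channel noise, NMDA voltage
dependence inside the traces (the Jahr–Stevens function is exposed as
`nmda_block()` but the mock's EPSP kernel is voltage-independent), or
morphology-dependent filtering beyond the two exponential profiles.
Passing tests therefore demonstrate that the **test machinery** —
protocols, feature formulas, scoring constants, search and calibration
algorithms, persistence — is correct on models with known ground truth;
they say nothing about any biophysical model's behavior.

Default study conditions: traces are sampled at dt = 0.025 ms (the
field-standard fixed step), step protocols use 500 ms delay and 1000 ms
duration, synaptic runs 150 ms delay with 400 ms of simulated time, the
PSP test samples 15 locations, and the oblique test probes 2 locations
on each of the default morphology's 3 obliques. At these sizes the full
test suite (including the 1000-trace and 200-tree property suites) and
the acceptance script each run in about a minute on one CPU.

## Numerical choices

* Time-weighted means use trapezoid quadrature with interpolated
  window edges; maxima are sample-based (traces are densely sampled).
* The step penalty is computed from the integer step count
  (floating-point exact).
* Amplitude grids are generated with `seq()` and compared with
  tolerances, never by exact equality against decimal literals.
* Bisection loops are bounded (weight calibration by `c_step_stop`
  with a hard iteration cap; the bAP rate search by `max_bisect`) so
  no pathological model can hang a test.
* All randomness (PSP location sampling, optional morphology jitter)
  flows through explicit seeds recorded in the result; every
  capability call is required to be deterministic, which is what makes
  per-amplitude/per-location runs order-independent and restartable.

## Known limitations

* The somatic feature registry covers the features used by the five
  tests, not a full feature-extraction catalogue; unknown names fail
  loudly rather than approximately.
* The behavioral block criterion can be satisfied without a true
  depolarized equilibrium (see above); inspecting the traces remains
  advisable, and the result files carry enough information to do so.
* The bAP strong/weak classification scheme — one class chosen at the
  most distal evaluable range and applied to every class-variant
  feature — is one defensible reading of a protocol that leaves class
  handling open.
* `--jobs` is accepted for interface compatibility but runs are
  sequential; the order-independence contract is tested instead, so a
  parallel backend could be added without changing results.
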
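---
title: "Resistive-pulse event analysis for conical track-etched nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistive-pulse event analysis for conical track-etched nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the analysis problem

In resistive-pulse sensing a single nanopore connects two electrolyte
reservoirs under a fixed bias. The open pore passes a steady ionic current
$I_0 = G \cdot V$; each analyte molecule that enters transiently reduces the
current, and every such *blockade event* is summarized by a handful of
scalar descriptors. For a conical track-etched pore the open-pore
conductance under bulk-like ion transport is

$$G = \frac{\kappa \, \pi \, d_t \, d_b}{4L},$$

with $\kappa$ the electrolyte conductivity, $d_t$ and $d_b$ the tip and base
openings and $L$ the membrane thickness. The `geometry` functions implement
this relation, its inverse (tip sizing from a conductance measurement, the
standard way to calibrate a freshly etched pore), the linear etch-time
calibration of the base opening, and the cone half-angle
$\alpha = \arctan\!\big((d_b - d_t)/2L\big)$. The half-angle formula is our
choice — only $\alpha$ values are conventionally quoted, not their defining
expression — and it reproduces the quoted angles of both reference pores
(0.4° and 0.8°) at one-decimal rounding. All geometry is SI internally;
nothing protects you from feeding nanometres where metres are expected
except reading the documentation, which is why the constructors validate
invariants ($d_b \ge d_t$, $L > 0$) but not magnitudes.

Conical pores with micrometre lengths have long dwell times but poor shape
resolution: different short DNA samples produce blockade-depth and duration
distributions that overlap almost completely. The analysis this package
automates is the standard rescue: characterize each event by *five*
features rather than the classical two, and let a support vector machine
use the extra geometry of the event shape — which a conical pore renders
asymmetric — to discriminate samples that the marginal distributions cannot.

## Trace conditioning

Raw traces (100–200 kHz sampling) are processed in a fixed order:

1. **Low-pass filtering.** A Butterworth filter, 2.5 kHz cutoff, order 2,
   applied forward and backward (`lowpass_butterworth()`). Zero-phase
   filtering preserves event onset positions, which the flank-slope features
   need; the price is that the amplitude response is the squared single-pass
   magnitude, so the gain at the nominal cutoff is 0.5, not $1/\sqrt2$ — the
   tests assert exactly this analytic value. Edge transients are suppressed
   by odd-reflection padding (several filter time constants long); without
   it, forward-backward filtering corrupts hundreds of samples at each end.

2. **Baseline correction.** Open-pore current drifts slowly. The baseline is
   estimated with a Savitzky–Golay smoother of polynomial order 1 and 2400
   *side* points (window 4801 samples ≈ 48 ms at 100 kHz; we read "side
   points" as the half-window). For order ≤ 1 on a symmetric window the
   Savitzky–Golay estimate equals the window mean, so
   `estimate_baseline_savgol()` computes it as an exact running mean with
   cumulative sums — O(n), hundreds of times faster on megasample traces
   than generic polynomial filtering, and verified against
   `signal::sgolayfilt()` to 1e-9 relative in the tests. At the trace edges
   the window is truncated symmetrically; the first and last 2400 samples
   are treated as edge-affected, and events overlapping them are discarded.
   Working on the *deviation* `baseline - current` makes blockades positive
   excursions, the sign convention used everywhere downstream.

The order-1 smoother reproduces any linear drift exactly, and a 4801-sample
window barely responds to a 100-sample event (the dip it induces under an
event is about `depth × event_samples / 4801`, ~2% of depth for a typical
1 ms event — one of the small biases discussed below). The baseline is
estimated from the filtered trace *including* events, in a single pass;
combined with a robust noise estimator this matches the single-pass
description of the original workflow.

## Event detection and the five features

Detection applies the 3σ rule (`detect_events()`): an event is any maximal
region of the deviation above $k_\mathrm{boundary}\sigma$ (default 1σ) that
contains at least one sample above $k_\mathrm{detect}\sigma$ (default 3σ).
The boundary multiplier is deliberately lower than the detection multiplier:
ending events at the 3σ re-crossing would truncate the flanks that the
slope features are fitted on. σ defaults to the robust estimate
$1.4826 \times \mathrm{MAD}$ of the deviation series, because a plain
standard deviation is inflated by the events themselves (the tests construct
a 5%-contaminated series where the plain estimate is >50% high while the
robust one stays within 10%). The plain estimator remains selectable for
fidelity comparisons. Events shorter than `min_dwell` (default 5 samples)
are discarded. Indices are 1-based with half-open intervals
`[start_idx, end_idx)`, the natural R convention.

Each retained event yields (`extract_features()`):

* **Δt** (`dwell_s`) — `(end_idx - start_idx) / rate`, the boundary-to-
  boundary width;
* **ΔI/I₀** (`rel_blockade`) — peak deviation divided by the *local*
  Savitzky–Golay baseline at the peak (drift is real, a global mean would
  bias depths);
* **AUC** (`auc`) — trapezoidal integral of the deviation over the event,
  in A·s (absolute units; a normalization choice, since the convention in
  published heat maps is not stated);
* **LS, RS** (`left_slope`, `right_slope`) — least-squares line slopes over
  the central 10–90% span of the falling and recovering flanks, in A/s.

Two details of the slope definition matter. First, fitting start-to-argmax
is unusable on flat-topped events: the deviation argmax lands anywhere on a
noisy plateau, so the fit spans a random plateau stretch and measures where
the noise peaked rather than how fast the current fell. Second, the lower
10% bound excludes the shallow smeared foot that the low-pass filter adds
below the detection boundary. The 10–90% span is the standard rise-time
convention; on an ideal triangular event it reproduces the exact closed-form
slopes ±2a/d, which the tests assert.

### Known measurement biases

Two biases of this (conventional) estimator set are worth stating because
the parameter-recovery tests quantify them rather than hide them:

* **Dwell smear.** The zero-phase 2.5 kHz filter extends each event edge
  outward; the 1σ boundary crossing then happens on the smoothed tail. On
  noise-free trapezoids spanning the benchmark's shape range the dwell bias
  runs from −0.28 ms (long events with shallow flanks, where the low
  threshold trims flank feet) to +0.22 ms (short events, where the smear
  dominates). For events near 1 ms this is within ±10–15%, but
  sub-millisecond events cannot be recovered to 10%: the acceptance suite
  records detection recall ≥ 95% (measured: 100%) *and* the fraction of
  events with both ΔI/I₀ and Δt within 10% of injected values, which
  plateaus near two thirds for exactly this reason. The bias is a property
  of threshold-crossing width under band-limiting, not of the
  implementation; removing it would require model-based pulse fitting,
  which is out of scope.
* **False positives.** The plain 3σ rule on long stretches of band-limited
  noise inevitably yields threshold upcrossings — about 18 per 8 s trace under the
  benchmark noise. They enter the feature table as shallow events at
  ΔI/I₀ ≈ 0.010, well below every injected event (≥ 0.02), and are kept:
  they are the honest output of the published rule, and the classifier
  sees them as label noise affecting both feature sets equally.

## The synthetic benchmark

No experimental recordings are publicly deposited, so every downstream
stage is validated against a generator (`make_benchmark_dataset()`) whose
defaults emulate the reported study conditions for three short DNA samples
measured with a 3 nm-tip pore at 500 mV:

| parameter | A10T10 | A40T40 | T40 | source |
|---|---|---|---|---|
| ΔI/I₀ center | 0.085 | 0.093 | 0.066 | reported centers |
| ΔI/I₀ sd | 0.025 | 0.025 | 0.025 | chosen (overlap, below) |
| Δt median (ms) | 1.07 | 0.95 | 1.29 | reported centers |
| Δt geometric sd | 1.65 | 1.65 | 1.65 | chosen |
| falling-flank scale | 0.12 | 0.25 | 0.50 | chosen (asymmetry) |
| recovering-flank scale | 0.50 | 0.25 | 0.12 | chosen (mirrored) |

The open-pore current is `G(κ=10 S/m, pore 1) × 0.5 V ≈ 0.18 nA`; Gaussian
noise has σ = 1.5 pA (one tenth of the central event depth), plus a 2 pA
sinusoidal drift (5 s period) and a small random walk, both far slower than
the baseline window. Events are trapezoids: linear fall, plateau, linear
recovery, with closed-form expected features — the reason for choosing a
trapezoid over a physical translocation model. Events are placed with at
least one Savitzky–Golay window between them and never inside the edge
zones, and the generator is bit-reproducible under a fixed seed.

### Why these spread parameters

The free parameters were set by variance budgeting against the qualitative
structure the benchmark must reproduce, and are fixed defaults, not knobs:

* **Marginal overlap.** With class centers 0.066/0.085/0.093 a common sd of
  0.025 keeps every pairwise histogram-intersection overlap above 0.5
  (normal-theory overlap $2\Phi(-d/2\sigma)$ ≥ 0.55 for the worst pair), so
  the two classical features genuinely cannot separate the classes — the
  premise of the whole exercise.
* **Δt–AUC coupling.** AUC ≈ depth × dwell × (1 − (rise+fall)/2). For the
  pooled correlation corr(Δt, AUC) to sit ≥ 0.8 as reported, dwell variance
  must dominate the AUC variance; geometric sd 1.65 (sdlog 0.5) achieves
  this against the depth CV of ~0.3.
* **Flank asymmetry as the class signal.** Class identity is injected
  predominantly into the flank features, making the "five features beat
  two" outcome reproducible *by construction* — a modeling choice,
  explicitly not a claim about the real samples. Flank **rates**
  (relative-blockade change per second) are drawn log-normally (sdlog 0.7)
  and independently of both depth and dwell: the speed of the current
  transition reflects the molecule's velocity through the sensing zone, not
  its residence time. This independence is what keeps the left and right
  slopes decorrelated. Two earlier parameterizations failed instructively:
  flank durations proportional to dwell make both slopes share the
  heavy-tailed depth/dwell factor (measured |corr(LS,RS)| ≈ 0.6), and even
  dwell-independent *durations* leave slopes proportional to depth. With
  independent rates the injected slopes are uncorrelated (measured ≈ 0.01),
  and the residual pooled correlation of the *measured* slopes
  (≈ −0.2…−0.3) comes from filter saturation: flanks faster than the
  2.5 kHz response are measured at the instrument limit `depth/T_filter`,
  which re-introduces a shared depth factor. Within single classes this
  saturation pushes |corr(LS,RS)| toward 0.45; the structural checks
  therefore evaluate the pooled feature table, and both views are computed
  by `run_pipeline()`.

### What the generator does not emulate

No 1/f noise, no multi-level blockades, no secondary depth mode (a second
ΔI/I₀ population is reported for one sample), no event-rate statistics (the
inter-event spacing is uniform slack, since no interval statistics are
published), no electrolyte-specific conductivity effects, and no 10 kHz
Bessel stage. Passing tests therefore demonstrate that the *pipeline*
recovers what was injected under realistic noise, drift and overlap — not
that real recordings would classify at the same accuracy.

## Statistics and classification

`density_histogram()` normalizes counts as $d_i = f_i/(n\,w_i)$ — bin
heights are comparable across samples of different sizes, and
$\sum_i d_i w_i = 1$ when the range covers the data. Conventional widths
are 0.01 for ΔI/I₀ and 200 µs for Δt (we read the published dwell bin width
"200" as microseconds, given millisecond-scale axes). Bins are left-closed,
right-open, anchored at 0. Correlations are Pearson throughout (the
published diagnostics are linear); zero-variance columns give NA with a
warning, never a silent 0. `regress_blockade_on_dwell()` is OLS of ΔI/I₀ on
Δt, and its R² equals the squared Pearson correlation — asserted as an
identity in the tests.

`train_eval_svm()` evaluates an RBF-kernel SVM (one-vs-one for the three
classes) by stratified 5-fold cross-validation. The published protocol
(split, kernel, scaling) is not stated, so the choices here are documented
defaults, not claimed reproductions: RBF because the event clouds are not
linearly separable; cross-validation rather than a single split because a
few hundred events per class leave large split variance; nested 3-fold grid
search over cost {1, 10, 100} and kernel width {0.05, 0.2, 0.8} inside each
training fold; features standardized with training-fold statistics only
(a leakage probe in the tests injects a held-out outlier and asserts the
scaling is untouched). `compare_feature_sets()` runs the two-feature
(ΔI/I₀, Δt) and five-feature sets on *identical* fold assignments so the
accuracy difference is paired. Everything is deterministic given a seed.

## Numerical choices and degenerate inputs

* Filter padding: odd reflection, `max(512, 6·rate/cutoff)` samples each
  side, capped at the trace length.
* Baseline edges: symmetric window truncation; edge zones flagged and
  excluded from event detection.
* Slope fits need ≥ 2 samples per flank span; events failing this are
  discarded with a logged reason, available as the `"discarded"` attribute.
* Detection with `merge_gap > 0` merges events separated by less than the
  gap; default 0 (off).
* Ties in the hyperparameter grid resolve to the first (cheapest) cell.
* Truncated draws (depth to [0.02, 0.5], dwell to [0.25, 8] ms) use
  rejection sampling; flank fractions are clipped into the feasible
  trapezoid region (each ≤ 0.7 of dwell, sum ≤ 0.85).
* Empty event lists, zero-event datasets and stats-only pipeline configs
  are all valid and covered by tests.

## Problem sizes

The default benchmark carries 150 events per class (~8 s of 100 kHz trace
per class, ≈ 2.5 M samples in total), which the full pipeline — filter,
baseline, detection, features, statistics and the paired SVM comparison —
processes in well under a minute; the test suite uses 120 events per class.
These sizes put ≥ 40 events per class in every cross-validation fold while
keeping the suite quick to run.

## Limitations

* Dwell times inherit the threshold-crossing bias described above;
  comparisons *between* samples measured with the same settings are
  unaffected, absolute dwell values carry the smear.
* The SVM accuracies measured on the benchmark characterize the synthetic
  conditions; they are not estimates of the accuracies attainable on real
  recordings, which depend on event populations this generator does not
  model.
* The conductance relation assumes bulk conductivity — no access
  resistance or surface-conduction corrections, which matter for tips
  below a few nanometres at low salt.
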
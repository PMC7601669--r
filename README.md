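# poretrace

Resistive-pulse event analysis for conical track-etched nanopores.

Single conical nanopores etched in polymer membranes detect individual
biomolecules as transient drops in ionic current, but their high aspect
ratio gives them poor resolution: short DNA samples produce
relative-blockade (ΔI/I₀) and dwell-time (Δt) distributions that overlap
almost completely. `poretrace` implements the full analysis chain that
rescues discrimination by characterizing each blockade event with **five**
features instead of two and handing them to a support vector machine:

* **geometry** — conical-pore conductance `G = κ π d_t d_b / (4L)`, tip
  sizing from a conductance measurement, etch-time calibration of the base
  opening `d_b = 2.5 t`, cone half-angle;
* **preprocessing** — zero-phase Butterworth low-pass (2.5 kHz, order 2)
  and Savitzky–Golay baseline correction (2400 side points, order 1) of
  drifting traces;
* **event detection** — the 3σ threshold rule on the baseline-corrected
  deviation, with a robust (MAD) noise estimator;
* **features** — per event: ΔI/I₀, Δt, area (AUC) and the left/right flank
  slopes (LS, RS), the latter asymmetric for conical pores;
* **statistics** — density-normalized histograms `d_i = f_i/(n w_i)`,
  Pearson correlation matrices, OLS regression of ΔI/I₀ on Δt;
* **classification** — stratified cross-validated RBF-SVM with nested grid
  search, comparing the two-feature and five-feature sets on paired folds;
* **synthetic data** — a trapezoidal-pulse trace generator with ground
  truth that emulates the study conditions (overlapping marginals,
  class-informative pulse asymmetry), so the whole pipeline is testable
  without experimental recordings.

## Worked example

```r
library(poretrace)

pore1 <- pore_geometry(d_t = 3e-9, d_b = 200e-9, L = 13e-6)
print(pore1)
#> Conical pore: d_t = 3 nm, d_b = 200 nm, L = 13 um, alpha = 0.43 deg
pore_conductance(10, pore1) * 1e9   # nS at kappa = 10 S/m
#> 0.3625

run <- run_pipeline(list(
  simulate = list(n_per_class = 100, seed = 42),
  classify = list(folds = 5, seed = 1)))
print(run)
#> poretrace run: 303 events across 3 classes
#>   A10T10: n = 100, R^2(rel_blockade ~ dwell) = 0.053
#>   A40T40: n = 103, R^2(rel_blockade ~ dwell) = 0.087
#>   T40: n = 100, R^2(rel_blockade ~ dwell) = 0.011
#> two features:  47.9%
#> five features: 71.3%
#> gain: +23.4 points
```

The run simulates three labeled traces (100 ground-truth events each, ~6 s
of 100 kHz recording per class), filters and baseline-corrects them,
detects events at 3σ, extracts the five features, and cross-validates the
SVM twice on identical folds. The classes are built to overlap heavily in
ΔI/I₀ and Δt — the two-feature accuracy (47.9%) sits well below the
five-feature accuracy (71.3%) because the class signal lives mostly in the
flank slopes. The per-class R² values (~0.01–0.09) show ΔI/I₀ is not
linearly predictable from Δt, and the pooled correlation matrix reproduces
the expected structure:

```r
cc <- run$stats$correlation_pooled
cc["dwell_s", "auc"]; cc["left_slope", "right_slope"]
#> 0.86   (dwell and area strongly coupled)
#> -0.22  (flank slopes essentially uncoupled)
```

Lower-level entry points (`lowpass_butterworth()`,
`estimate_baseline_savgol()`, `detect_events()`, `extract_features()`,
`analyze_trace()`, `read_trace()`/`write_trace()`) expose every stage
individually; see the package vignette for the model, the measurement
biases of threshold-crossing dwell times, and the design of the synthetic
benchmark.

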
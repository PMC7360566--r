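---
title: "Methods: Bliss synergy analysis for 2D/3D combination screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bliss synergy analysis for 2D/3D combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
library(dplyr)
```

## The analysis problem

High-throughput pairwise drug-combination screens measure cell viability (and
imaging proxies for growth) in 384-well plates across a grid of dose
combinations, in planar (2D) and spheroid (3D) cultures of cancer cell lines.
The scientific questions are: which drug pairs kill more cells than expected
from their single-agent effects (synergy), which of those also reduce
viability to a therapeutically meaningful level (synergistic *and*
effective), and how consistently do different readouts and culture formats
answer these questions.

`synscreen` implements that analysis end to end: per-plate vehicle
normalization, single-agent dose-response summaries (censored IC20, log-dose
AUC), Bliss-excess scoring of 5 × 5 dose matrices, the joint
synergy-viability classifier, cross-readout agreement, and reproducibility
metrics — plus a synthetic screen generator with known ground truth, so every
stage is testable without access to raw screen data.

## Normalization

All treatment effects are expressed relative to the solvent-only (vehicle)
wells of the same plate, readout and timepoint:

$$V = \frac{\text{raw}}{\overline{\text{raw}}_{\text{vehicle}}}$$

so vehicle = 1 by construction and the mean of the normalized vehicle wells
on a plate is exactly 1. Values above 1 (growth stimulation or noise) are
*not* clamped at this stage; clamping is a synergy-scoring decision (below).
Vehicle wells are pooled per plate regardless of solvent type (DMSO vs
water): solvent-specific matching is not implemented because nothing in the
assay model requires it and it would halve the vehicle-well count per
stratum. Positive-control wells are normalized like any other well but enter
only quality-control reporting, never the synergy math.

For kinetic imaging readouts, `normalize_kinetic()` additionally references
time zero: the value is the fold-growth of treated wells relative to the
fold-growth of vehicle wells over the same interval.

## Single-agent dose-response

`fit_4pl()` fits the four-parameter logistic inhibition curve

$$f(d) = \text{lower} + \frac{\text{upper} - \text{lower}}
{1 + (d/\mathrm{EC}_{50})^{h}}$$

by bounded Levenberg–Marquardt least squares with multi-start
initialization: the EC50 grid visits every tested non-zero dose, the slope
starts at 0.5, 1 and 2, and the asymptotes start at the response extrema.
The lowest residual sum of squares wins; ties break to the smallest |h|.
Bounds keep asymptotes in [0, 1.5] (supra-vehicle responses occur in real
screens and are permitted) and h in [0.05, 10]. A response vector constant
across doses yields a flat fit whose IC is reported as `not_reached`.

Two summary statistics are derived analytically from the fit:

* **IC20** — the dose where the curve crosses relative viability 0.8, solved
  from the closed-form 4PL inverse, then *censored* to the tested range
  (0.01–20 µM by default): `below_range`, `above_range`, or `not_reached`
  when 0.8 lies outside the open asymptote interval. Solving the fitted
  curve, rather than interpolating raw points, is what makes the censoring
  categories well defined.
* **AUC** — the mean fitted viability over a uniform grid in log10 dose
  (trapezoid rule, 201 points, divided by the log-range width). This
  convention is bounded (1 = no effect), unit-free, and comparable across
  drugs with different potencies, which is what a cross-drug potency ranking
  needs. With 201 points the trapezoid error is far below the assay noise
  floor (the suite checks agreement with a 10^5-point integration).

## Bliss synergy scoring

The Bliss independence reference for two non-interacting drugs with
fractional effects $E_A, E_B$ is $E_{AB} = E_A + E_B - E_A E_B$; with
$E = 1 - V$ this is equivalent to multiplying relative viabilities,
$V_{AB} = V_A V_B$. The **Bliss excess** is kept on the viability scale,

$$\text{excess} = V_{\text{obs}} - V_A V_B,$$

so that *negative* excess means more killing than expected, i.e. synergy —
the same sign convention used when combinations are classified by
"Bliss excess < 0". The effect-scale and viability-scale formulations are
algebraically identical; the test suite property-checks the identity on
10^4 random inputs.

Scoring decisions that the model itself does not fix:

* **Single-agent values come from the matrix's own dose-zero edges** (same
  plate, same biological replicate), not from the separate single-drug
  screen. This is what makes per-replicate scoring coherent, and the 5 × 5
  design embeds the edges precisely for this purpose.
* **Clamping**: single-agent viabilities are clamped to [0, 1] before the
  product — an unclamped edge above 1 would make the expected viability
  exceed 1 and manufacture spurious synergy from noise. The observed
  combination viability is left unclamped. Clamping activations are logged.
* **Per-replicate scoring, then averaging**: Bliss grids are computed per
  biological replicate from technical-replicate means, then averaged
  cellwise across replicates (with cellwise SD); a dose pair missing from
  one replicate is scored from the remaining one.
* **Matrix summary**: the matrix-level score is the mean excess over the 16
  non-zero dose pairs; single-agent edge cells are excluded from both the
  mean excess and the mean viability so that the 2D-vs-3D comparison is
  about combination response, not single-agent potency.

A combination is **synergistic** when its matrix-mean excess is strictly
below 0, and a dose pair is **synergistically effective** when its excess is
strictly below 0 *and* its observed combination viability is at or below
0.5. The inclusive bound at 0.5 follows the definition "viability reduced to
at most 50% of vehicle"; the difference to a strict bound matters only for
values exactly at 0.5 and is surfaced as a configurable threshold.

## Agreement and reproducibility

Cross-readout agreement uses synergy-call sets per (readout, culture
format): `unique_calls()` reports calls made by one readout and no other.
Group comparisons use two-tailed t-tests (Welch by default; the classic
equal-variance Student test is an option) with the usual star convention at
p ≤ 0.05 / 0.01 / 0.001 and no multiple-testing correction, matching
screen-analysis practice of reporting raw p-values. The 2D-vs-3D viability
comparison is unpaired, because wells and plates differ between formats.

Technical variability is the coefficient of variation (sample n−1 SD over
mean — with 2–4 replicates the n-vs-n−1 choice is material, so one
convention is used everywhere) per condition, biological replicate and
readout; an overall CV is the unweighted mean of condition CVs per
(biological replicate, readout). Intra-screen reproducibility correlates
biological replicates 1 and 2 on shared conditions; inter-screen
reproducibility correlates single-agent doses shared between the
single-drug screen and the combination screen's edges.

## The synthetic screen generator

`generator_config()` emulates the screen design: 3 colorectal cancer cell
lines (HCT-116, HT-29, SW-620) × 2 culture formats, a 7-drug panel, an
8-dose single-agent screen log-spaced over 0.01–20 µM, all 21 pairwise
5 × 5 matrices (vehicle + 4 non-zero doses per drug, the 4 doses drawn from
the single-agent series as combination doses were selected from single-agent
response in the screen design), 4 technical × 2 biological replicates, 48 h
endpoint.

Ground truth is a Hill curve per (drug, cell line, format) and an additive
Bliss deviation δ per (pair, cell line, format):

$$V_{AB}(d_a, d_b) = \mathrm{clamp}\big(V_A(d_a)\,V_B(d_b) + \delta,\; 0,\; 1.5\big)$$

so the true Bliss excess equals δ exactly wherever the clamp is inactive —
parameter recovery becomes an identity check, and `truth_table()` computes
all expectations in closed form. δ is uniform across the 4 × 4 interior by
default; real synergy is often dose-dependent, but no functional form is
established, so dose-dependence is deliberately not modelled.

Default parameter choices, made once as field-realistic conditions:

* Hill parameters give the potency ordering seen in colorectal screens of
  this panel (MEK inhibitor most potent, TAK1 inhibitor second, PARP
  inhibitor weakest), mild per-cell-line potency shifts, and spheroids
  slightly less sensitive than monolayers except to MEK inhibition.
* Multiplicative Gaussian noise on raw signals, sd 0.05 in 2D and 0.08 in
  3D — spheroid readouts are noisier in practice.
* Injected deviations |δ| ≤ 0.2, the magnitude range where screen-scale
  Bliss heatmaps typically live.
* Raw-scale constants (vehicle luminescence 8192 counts; imaging scales 64,
  512, 128) are powers of two. This is a purely numerical choice: scaling by
  a power of two and dividing by the vehicle mean are then exact in IEEE
  floating point, so a zero-noise screen normalizes to the true viability
  bit-for-bit and the Bliss null scores exactly zero — which is what makes
  strict-inequality boundary behaviour (excess < 0) testable at all.
  Normalization itself is scale-invariant, so the constants carry no
  statistical content.

Secondary readouts are coupled to true viability: confluency as
$V^{0.8}$ (confluent area tracks live-cell count sublinearly), spheroid
size as $V^{1/3}$ (a diameter whose volume tracks viable-cell count), and
cell-death signals near baseline unless a drug is flagged apoptotic. This
reproduces the qualitative structure of real screens — viability correlates
strongly with confluency and only weakly with death readouts.

**What the generator does not emulate**: spatial plate artefacts (edge
effects, gradients), solvent-specific vehicle behaviour, spheroid geometry
and disaggregation, dose-dependent interaction surfaces, and
heavier-than-Gaussian outliers. Passing tests therefore demonstrate
correctness of the *computations* under the stated noise model, not
robustness to every failure mode of real plates.

## Numerical choices and degenerate inputs

* Dose matching to grid positions uses relative tolerance 1e-9 (doses are
  exact printed values; the tolerance only absorbs representation error).
* Missing grid cells (e.g. a dose pair dropped from one replicate by a
  dispensing error) are carried as explicit `NA` through every downstream
  mean/SD/count, with a warning at assembly; a matrix with a missing edge
  cell propagates `NA` to the excess cells that depend on it.
* A flat response vector yields a flat fit (`hill = NA`) rather than an
  error; ICs on it report `not_reached`.
* Zero-variance inputs to correlation and zero-mean inputs to CV are
  errors, not silent `NA`s — both indicate assay failure upstream.
* Fit ties (equal RSS) break to the smallest |hill|, preferring the
  least-steep explanation.

## Problem sizes used in the test suite

Stochastic checks use sizes chosen to make sampling error negligible
relative to the tolerances being asserted: 200 simulated screens per
injected δ for recovery coverage (a single-pair screen with 4 technical ×
2 biological replicates each), 25 + 25 screens for the
sensitivity/specificity check at |δ| = 0.15, and single full-design screens
(21 pairs × 3 cell lines × 2 formats) for design-count and pipeline checks.
The recovery check compares each run's estimate to the injected δ at three
*empirical* standard errors of the estimator: the naive
σ/√(replicates × cells) expression understates the true standard error
because excess cells share single-agent edge values and the per-plate
vehicle divisor, and the Monte Carlo SE accounts for both.

## Worked example

```{r example, eval = FALSE}
cfg <- example_screen_config(seed = 1)
ds <- simulate_screen(cfg)
bundle <- run_pipeline(run_config(dataset = ds, out_dir = "reports"))
counts <- report_counts(bundle)
counts$dose_points
counts$synergistic_combinations
head(counts$effective_ranking)
```

`example_screen_config()` seeds a realistic interaction landscape (PI3K+MEK
and PI3K+TAK1 synergy, chemotherapy synergy in monolayers, MEK-inhibitor
combinations more synergistic in spheroids, one antagonistic pair, and a
majority of non-interacting pairs). The README shows the printed output of
this exact example.

## Known limitations

* Synergy calling is a strict sign test on the mean excess, with no
  significance threshold — a matrix whose true excess is 0 is called
  synergistic about half the time under noise. This mirrors the screen
  definition being implemented; users wanting calibrated calls should gate
  on `sd_excess` or replicate counts.
* The 4PL fit reports no confidence intervals; technical-replicate spread is
  summarised separately via CV.
* No plate-position bias correction or background subtraction is applied.
* The AUC and IC conventions are fixed by this package's definitions;
  numeric agreement with other software's AUC/IC values requires matching
  conventions, not just the same data.
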
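# synscreen

Analysis of high-throughput pairwise drug-combination screens run in
384-well plates on planar (2D) and spheroid (3D) cancer cell cultures.

Combination screens ask two distinct questions about every drug pair:
does the combination kill *more than expected* from the single agents
(synergy), and does it reduce viability to a level that matters
(effectiveness)? `synscreen` answers both, across readouts (ATP viability,
confluency, spheroid size, cell-death signals) and culture formats, and
quantifies how reproducible and readout-dependent the answers are.

## The model

All well signals are normalized to the solvent-only (vehicle) wells of their
own plate, so vehicle = 1. Single-agent response is summarised by a
four-parameter logistic fit

    f(d) = lower + (upper − lower) / (1 + (d/EC50)^hill)

with an analytically solved, range-censored **IC20** (reported as
`below_range` / `above_range` / `not_reached` when outside the tested
0.01–20 µM range or never crossed) and a log-dose **AUC** (mean fitted
viability over log10 dose; 1 = no effect).

Combination response in each 5 × 5 dose matrix (vehicle + 4 doses per drug)
is scored against the **Bliss independence** reference. For fractional
effects E = 1 − V the Bliss expectation is `E_A + E_B − E_A·E_B`;
equivalently, expected combination viability is the product `V_A·V_B`. The
per-dose **Bliss excess** is kept on the viability scale,

    excess = V_obs − V_A·V_B        (negative ⇒ synergy)

with single-agent viabilities taken from the matrix's own dose-zero edges
(same plate, same biological replicate) and clamped to [0, 1] before the
product. Grids are scored per biological replicate, then averaged cellwise.
A combination is **synergistic** when its matrix-mean excess is below 0, and
a dose pair is **synergistically effective** when its excess is below 0
*and* combination viability is at or below 0.5 — the joint classifier that
separates interesting synergies from weak ones.

Agreement and reproducibility use Pearson correlations (replicate 1 vs 2;
single-drug screen vs combination-screen edges), per-condition coefficients
of variation, readout-exclusive synergy-call sets, and two-tailed t-tests
with the `*`/`**`/`***` convention at p ≤ 0.05/0.01/0.001.

A synthetic screen generator (`simulate_screen()`) reproduces the full
design — 3 cell lines × 2 formats, 7 drugs, 8-dose single-agent screen, all
21 pairwise 5 × 5 matrices, 4 technical × 2 biological replicates — from
ground-truth Hill curves plus an injected Bliss deviation δ per pair, so
the true excess is known exactly and every pipeline stage is testable
(`truth_table()` gives closed-form expectations).

## Worked example

```r
library(synscreen)
library(dplyr)

cfg <- example_screen_config(seed = 1)   # 7 drugs, seeded synergy landscape
ds  <- simulate_screen(cfg)
ds
#> <screen_dataset> 64944 well records
#>   cell lines: HCT-116, HT-29, SW-620
#>   formats:    2D, 3D | readouts: celltox, confluency, nucview, spheroid_size, viability
#>   plates:     258 | bio reps: 1, 2

bundle <- run_pipeline(run_config(dataset = ds, out_dir = "reports"))
counts <- report_counts(bundle)

filter(counts$dose_points, readout == "viability")
#>   readout   culture_format n_dose_points n_excess_negative n_missing fraction_negative
#> 1 viability 2D                      1008               551         0             0.547
#> 2 viability 3D                      1008               578         0             0.573
```

1008 = 21 pairs × 16 non-zero dose pairs × 3 cell lines: the per-format
denominator of combination dose points, derived from the design. About half
of all dose points show negative Bliss excess — null pairs scatter evenly
around zero under noise, and the seeded synergies add the rest.

```r
norm <- normalize_dataset(ds)
summarize_dose_response(norm) |>
  filter(cell_line == "HCT-116", culture_format == "2D") |>
  select(drug, lower, log10_ec50, hill, ic_status, ic_dose, auc)
#>   drug  lower log10_ec50  hill ic_status   ic_dose   auc
#> 1 5-FU  0.351      0.613 1.00  value        1.69   0.837
#> 2 5Z    0.201     -0.964 1.62  value        0.0544 0.451
#> 3 OLA   0          2.12  0.833 above_range NA      0.954
#> 4 OXA   0.192      0.150 1.19  value        0.577  0.720
#> 5 PAL   0.464      0.406 1.47  value        1.94   0.871
#> 6 PD    0.148     -1.55  1.54  value        0.0151 0.286
#> 7 PI    0.241     -0.452 1.25  value        0.146  0.590
```

The MEK inhibitor PD is the most potent drug (IC20 ≈ 0.015 µM, lowest AUC);
the weak PARP inhibitor OLA never reaches 20% inhibition inside the tested
range, so its IC20 is censored as `above_range`.

```r
head(filter(counts$effective_ranking, readout == "viability",
            culture_format == "2D"), 4)
#>   cell_line combination n_effective mean_excess
#> 1 HCT-116   OXA + PD             14     -0.0423
#> 2 HCT-116   PD + PI              14     -0.138
#> 3 SW-620    PAL + PD             14     -0.0999
#> 4 SW-620    PD + PI              14     -0.139
```

`n_effective` counts dose pairs that are simultaneously synergistic
(excess < 0) and strongly growth-inhibiting (viability ≤ 0.5) — here the
MEK-inhibitor combinations dominate, as seeded.

`run_pipeline()` also writes tidy CSV reports (normalized values,
dose-response table, synergy summaries and per-dose grids, call sets, CV and
correlation tables), a JSON manifest and a run log under `out_dir`.

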
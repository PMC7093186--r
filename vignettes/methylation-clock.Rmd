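---
title: "Building a targeted bisulfite methylation clock for the naked mole-rat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a targeted bisulfite methylation clock for the naked mole-rat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrclock)
```

## The problem and the model

Chronological age is unknown for wild-caught naked mole-rats and for many
captive animals without pedigree records.  DNA methylation at a subset of
CpG dinucleotides drifts steadily with age, and deep targeted bisulfite PCR
sequencing of a dozen amplicons — a few dozen CpGs in total — is enough to
read that drift out.  `nmrclock` implements the complete analysis, from
(simulated) sequencing reads to a cross-validated age predictor and
tissue-rate comparison.

The generative model the analysis assumes is deliberately minimal.  At CpG
$j$ in sample $i$:

$$ m_{ij} = \mathrm{clamp}\!\left( m_{0j} + s_j \, r_{t(i)} \,
\mathrm{age}_i + \varepsilon_{ij},\; 0, 1 \right), \qquad
\varepsilon_{ij} \sim \mathcal{N}(0, \sigma_b^2) $$

* $m_{0j}$ — baseline methylation fraction at birth-age zero;
* $s_j$ — drift slope in fraction per week, zero at non-aDMP sites;
* $r_t$ — tissue rate multiplier, liver $= 1$ by convention;
* $\sigma_b$ — per-sample, per-site biological scatter.

Sequencing then observes a binomial draw around $m_{ij}$: each read
reports the CpG cytosine as C (methylated) or, after bisulfite conversion,
T (unmethylated).  The clock inverts the drift multivariately with an
elastic net,

$$ \hat{\mathrm{age}}_i = \beta_0 + \sum_j \beta_j m_{ij}, \qquad
\min_\beta \frac{1}{2n}\,\mathrm{RSS} + \lambda\left( \alpha \lVert \beta
\rVert_1 + \tfrac{1-\alpha}{2} \lVert \beta \rVert_2^2 \right), $$

fitted by cyclic coordinate descent with the soft-threshold update
(implemented in C++ in this package; `glmnet` is used only as an
independent cross-check in the test suite).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `slope_range` | 3–7 × 10⁻⁴ | fraction/week | over a ~1,100-week lifespan this spans a 0.33–0.77 total drift, the magnitude at which a CpG is comfortably detectable at n = 24 without being saturated |
| `sigma_b` | 0.03 | fraction | biological scatter around the drift line; comparable to the binomial noise at 200× |
| `target_coverage` | 200 | reads/region | typical targeted bisulfite amplicon depth; safely above the 50× filter |
| `min_coverage` | 50 | reads | sites under 50 informative reads are too noisy; a site at exactly 50 is **kept** (the filter discards strictly below) |
| `conversion_efficiency` | 0.99 | probability | a 1% conversion failure is a realistic kit efficiency; it inflates observed methylation by $(1-p)\cdot 0.01$ |
| `sequencing_error_rate` | 0.001 | per base | MiSeq-class substitution rate; an erroneous base at a CpG (A/G/N) is excluded from both counts rather than called unmethylated |
| `tissue_rates` | liver 1, skin 0.6 | — | skin accumulates drift more slowly than liver; 0.6 is the package's planted skin rate, which the rate-recovery checks then re-estimate |
| `alpha_mix` | 0.5 | — | equal L1/L2 mix, the convention of multi-tissue methylation clocks; exposed as a knob |
| `n_lambda` | 100 | — | penalty grid resolution, log-spaced over $[\lambda_{max}\cdot 10^{-4}, \lambda_{max}]$ |
| `admp_alpha` | 0.05 | — | per-site screen threshold, **strict** inequality, no multiple-testing correction (the selection is a raw p < 0.05 screen by design) |

## What the simulator does and does not emulate

`make_panel()` builds amplicon references whose *only* CG dinucleotides are
the planted CpG sites (background sequence is scanned and repaired), so a
substring scan of the FASTA is an exact oracle for the panel geometry.
`simulate_reads()` emits single-end reads spanning the whole amplicon from
the original-top strand: every read then informs every CpG of its region,
which is the analytically convenient form of a targeted amplicon assay.
Real paired-end 150 bp chemistry, PCR duplicates, primer artefacts,
M-bias, quality-score profiles and indels are *not* modelled; read mapping
is replaced by direct bisulfite-space assignment to the amplicon panel
(Hamming distance against C→T-collapsed references with CpG positions as
C/T wildcards, discarding reads beyond a 10%-of-length mismatch ceiling).
Sequencing error substitutes a base with one of the other three uniformly.

Cohort ages are drawn uniformly over the stated range.  Real colonies have
lumpy age distributions; uniform ages maximise regression leverage, so
passing recovery checks here says the *method* works under its assumed
model, not that any real cohort carries this much information.  Similarly,
$\sigma_b = 0.03$ makes single CpGs substantially cleaner than typical
real tissue panels, where single-site age correlations around 0.8–0.9 and
week-scale errors of several hundred weeks are the norm; the package's
synthetic checks therefore exercise correctness and calibration, not
real-data error magnitudes.

`simulate_counts()` is a count-level shortcut (binomial at target coverage,
with conversion-failure inflation) used where an analysis consumes the
matrix rather than reads; `simulate_reads()` + `extract_methylation()` is
the full path and the two agree read-for-read when sequencing error is off.

## Numerical choices

* **Coordinate descent** converges when the largest absolute coefficient
  change in a full sweep drops below `tol`.  For cross-validation paths the
  threshold is scaled to the response: $10^{-4}\,\mathrm{sd}(y)$ — with
  week-scale ages an absolute $10^{-7}$ would demand machine-precision
  convergence of coefficients worth hundreds of weeks and waste thousands
  of sweeps for no change in any reported metric.  The final model is
  refitted at $10^{-6}\,\mathrm{sd}(y)$.  Non-convergence at `max_iter` is
  an error reporting the last delta.  The objective is asserted (in the
  test suite) to be non-increasing across sweeps.
* **Penalty selection** uses leave-one-out internal folds — deterministic
  at n = 24, no random fold assignment — and the 1-SE rule, with ties
  resolved toward the larger penalty (more shrinkage).  $\lambda_{max} =
  \max_j |x_j^\top (y - \bar y)| / (n\alpha)$ zeroes every coefficient;
  weights within float noise of that stationarity boundary are treated as
  zero when counting active sites.
* **Standardisation** is recomputed inside every training fold (unit
  variance, n−1 denominator); zero-variance sites are dropped for that
  fold.  Reported clock weights are back-transformed to the original
  fraction scale.
* **Leakage**: inside `loocv_predict()` the held-out sample contributes
  nothing to imputation means, standardisation, penalty selection or
  coefficients — hyperparameters are re-selected in every fold.
* **Missing data** are imputed with training-set per-site means at the
  clock stage and dropped pairwise at the per-site screen; no imputation
  feeds the selection.
* **Degenerate inputs**: a site with under 3 non-missing pairs is unusable;
  zero variance in fractions gives slope 0 and p-value 1; identical
  training rows collapse the clock to the mean training age; predictions
  are never clamped, so negative predicted ages are possible and reported.
* **Coordinates**: BED is 0-based half-open; coverage files and site ids
  (`scaffold:pos`) are 1-based inclusive, matching each format's de facto
  dialect.

## Design decisions on genuinely open points

* Ages are regressed untransformed in weeks (no log-age transform): all
  errors of interest are reported in raw weeks and the target readout is
  linear.
* Week-scale single-CpG errors (RMSE/MAD/MAE) come from the *inverse*
  regression (age on methylation) and are in-sample, matching a plain
  fitted-linear-model reading of a single-site calibration plot.
* The per-site test is the t-test on the OLS slope; for simple regression
  this is identical to the correlation test.
* The shipped clock is trained on the first liver batch only; the second
  batch and the skin cohort are pure test sets.  No site re-filtering is
  applied when predicting skin.
* The skin rate readout is the OLS slope of predicted on actual age with a
  t-based 95% CI, reporting whether the CI excludes 1.

## Problem sizes used in the checks

The package's own verification runs use the full study geometry — 12
amplicons / 51 CpGs / 23 drift sites, 24 + 19 liver and 20 skin samples —
with count-level simulation and 20 replicate seeds for the recovery
statistics, and read-level simulation (≈ 1.5 × 10⁴ reads per cohort) for
the extraction checks and the end-to-end run.  Null calibration uses 2,000
no-drift sites.  These sizes keep the whole suite around two minutes while
leaving every statistical check comfortably powered.

## Known limitations

* The linear drift model saturates at 0 and 1; very old animals at
  fast-drifting CpGs compress against the clamp, which mildly flattens the
  predicted-vs-actual slope (visible as in-batch slopes slightly below 1).
* The elastic net's exact coefficients depend on conventions the field
  rarely pins down (mixing weight, penalty-selection rule,
  standardisation); results driven by those conventions should be read
  with tolerance.
* No covariates (sex, batch, litter) are modelled anywhere, and no
  multiple-testing correction is applied at the screen — both deliberate
  fidelity choices, not recommendations for genome-wide designs.
* Real-data ingestion expects per-CpG count tables (Bismark coverage
  dialect); the package does not map reads against a genome.
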
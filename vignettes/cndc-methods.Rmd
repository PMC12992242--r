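---
title: "Methods: critical N dilution curves, NNI diagnosis, and trial analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: critical N dilution curves, NNI diagnosis, and trial analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cndc)
```

## The model

A crop population dilutes its nitrogen as it accumulates mass: the minimum
N concentration compatible with maximum growth falls with biomass as a
power law,

$$N_c = a_c \cdot DW^{-b},$$

with $N_c$ in g N per kg dry matter, $DW$ the population dry matter in
t/ha, $a_c$ the critical concentration at $DW = 1$ t/ha, and $b > 0$ the
dilution exponent. The nitrogen nutrition index $NNI = N_t / N_c$ compares
the measured concentration $N_t$ to the critical one at the same biomass;
1 is adequacy, above 1 luxury uptake, below 1 deficiency.

The curve is constructed from a multi-rate fertilization trial in three
steps, applied independently at each sampling stage:

1. **Classification.** Block-level biomass is compared across N-rate
   treatments (one-way ANOVA, then pairwise tests against the
   maximum-biomass treatment). Treatments statistically indistinguishable
   from the top form the *non-limited* group (on the biomass plateau); the
   rest are *N-limited* (biomass still rising with N).
2. **Critical point.** Treatment-mean N concentration is regressed on
   treatment-mean biomass over the limited group; the line's value at the
   non-limited group's mean biomass ($DW_{ref}$) is the stage's critical
   concentration.
3. **Curve fit.** The power law is fitted through the per-stage critical
   points.

Stages that fail step 1 (no limited treatments, or fewer than two) are
dropped from step 3 with a logged reason rather than failing the run; a
curve needs at least two surviving stages.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 0.05 | — | significance level of the pairwise classification |
| `method` | `"welch"` | — | pairwise test vs the top treatment (`"tukey"` HSD as alternative) |
| `part` | `"whole_plant"` | — | plant fraction the curve is built on (`"reproductive"` supported throughout) |
| `tolerance` | 0 | NNI units | half-width of the `optimal` band around NNI = 1 |
| `include_root` | `FALSE` | — | whether root records count toward whole-plant mass |

The classification procedure behind "increased significantly" is
underdetermined in the field literature: we default to Welch t-tests
against the top-biomass treatment because they are robust to variance
heterogeneity across rates and easy to audit, and expose Tukey HSD for
users who prefer a family-wise procedure. With four blocks either test has
limited power; `alpha` trades false plateau membership against false
limitation.

## Aggregation choices

Plot-level organ records are the unit of entry (the randomized-block
structure must survive aggregation, since classification runs on
block-level biomass). Block values are computed first, treatment summaries
second. Whole-plant concentration is the biomass-weighted mean of organ
concentrations — total N over total dry matter — and the *treatment*
concentration is likewise biomass-weighted over blocks. The weighted
convention is what makes two exact identities hold simultaneously:
`n_uptake = biomass × n_conc` at every aggregation level, and whole-plant
uptake = vegetative + reproductive uptake. A plain block mean of
concentrations would break both by a term of order the squared CV.

Roots are excluded from whole-plant mass by default: $a_c$ is
conventionally quoted at 1 t/ha of *aboveground* dry matter. The schema
carries an optional `root` organ class and `include_root = TRUE` expresses
the other convention.

## The synthetic trial generator

The generator emulates the study conditions the package is designed for:
six N rates (0–300 kg/ha in 60 kg/ha steps), four blocks, four stages
(initial flowering → boll opening) with potential whole-plant biomass 3.5,
7, 11 and 14 t/ha, a true curve with $a_c = 26.936$, $b = 0.284$ (realistic
whole-plant cotton coefficients), and 5% CV multiplicative lognormal
replicate noise. Noise is lognormal, not additive Gaussian, so biomass and
concentrations stay positive at any CV.

**Biomass** responds to effective N supply (soil supply, default 60 kg/ha,
plus fertilizer) through a Michaelis-type factor (half-saturation
120 kg/ha) hard-plateaued at the optimal rate (240 kg/ha). The hard plateau
is deliberate: rates at or above the optimum share *exactly* the stage's
potential biomass, so they form a clean non-limited group and the gain from
240 to 300 kg/ha genuinely vanishes, as observed in well-run trials.

**Concentration.** At the optimal rate the plant sits exactly on the true
curve. Supra-optimal rates are lifted above it by
`luxury_slope × relative surplus` (luxury uptake without biomass gain).
Sub-optimal rates are placed on a *straight line through the stage's true
critical point* $(W_{max},\, a_c W_{max}^{-b})$ with slope equal to the
curve tangent divided by $1 + \texttt{deficiency\_slope}$. Because the
curve is convex and the line is shallower than its tangent, these points
lie strictly below the curve everywhere left of the plateau — the
sub-critical depression regime. This construction was chosen over a
multiplicative depression because it makes the intersection-rule estimator
*exact* on noiseless data: the limited points are collinear and their line
passes through the true critical concentration at $DW_{ref}$, so the full
pipeline recovers $(a_c, b)$ to numerical precision, and any recovery error
under noise is attributable to noise alone. With
`deficiency_slope = 0` (and `luxury_slope = 0`) the generator instead puts
every point exactly on the curve — useful for testing the curve itself, but
note the construction then changes qualitatively rather than continuously
as the slope approaches zero; this discontinuity is accepted and
documented.

What the generator does *not* emulate: year × weather effects on curve
parameters (years differ only by noise draws unless configured otherwise),
within-plot sampling error structure, stage-dependent luxury/deficiency
intensity, organ-specific dilution curves (reproductive concentrations are
a fixed ratio of whole-plant ones, so the reproductive-part pipeline runs
but has no independent power-law truth), and any covariance between yield
and the concentration noise. Passing recovery tests therefore demonstrates
the estimator chain is correct and noise-stable — not that real trials
satisfy its assumptions.

## Numerical choices

* **Power fit.** Nonlinear least squares on the original scale
  (Levenberg–Marquardt, `minpack.lm`), initialized from the log–log OLS
  solution; log–log alone would minimize relative rather than absolute
  error. Both R² variants are reported; original-scale is primary. On
  non-convergence the log–log coefficients are returned, flagged.
* **Zero-variance fallback.** Noiseless replicates make t-tests undefined;
  classification then compares means at 1e-9 relative tolerance.
* **Linear-plateau fit.** For a fixed breakpoint $c$ the model
  `y = intercept + slope × pmin(x, c)` is linear, so SSE($c$) is profiled
  over a 200-point grid between min(x) and max(x) and refined by
  golden-section search in the bracketing cells. Deterministic,
  oracle-checkable, and free of the starting-value sensitivity of generic
  segmented-regression optimizers. The grid includes max(x), where the
  model degenerates to a straight line, so the piecewise fit can never be
  worse than the best line.
* **Validation pairing.** Predicted = curve at each hold-out plot's
  observed biomass; observed = that plot's measured concentration; all
  treatments and stages pooled. A `blocks_per_treatment` option subsamples
  replicates for designs whose validation used fewer blocks than were sown.
* **Economic optimum.** Closed-form vertex of the concave benefit
  quadratic; the benefit transform applies (seed cotton price − harvest
  cost) to the yield quadratic and subtracts the N cost, by default urea
  price / urea N fraction (3.8/0.464 ≈ 8.19 yuan per kg N), with the quoted
  pure-N price (8.3) as an override since both conventions circulate.

## Open design decisions

* **Relative yield** has no universal definition; it is computed as the
  treatment mean divided by the maximum treatment mean within the same
  year. Fits of RY on NNI are per year by default (`pool = TRUE` to pool).
* **Stability index**: conventions differ between Y/SD and SD/Y; the
  default is SI = mean/SD (larger = more stable), with
  `convention = "sd_over_y"` for the reciprocal. The SD is taken across a
  treatment's year (or replicate-year) observations, not across treatments:
  a between-treatment SD could not yield per-treatment indices.
* **Harvest index** is seed cotton yield over whole-plant biomass × 100
  (both in kg/ha), as conventional in cotton N-response work, even though a
  lint-based dimensionless HI exists.
* **Lint percentage** is treated as a fraction internally; percent inputs
  (> 1) are auto-converted in `nue_indices()`.
* **NNI level**: treatment means by default, per-block diagnosis via
  `level = "block"`.

## Problem sizes and limitations

The test suite and the acceptance script run the generator at its default
size (6 × 4 × 4 × 2 organs = 192 plot records per year) and use 20 seeds
for the noisy-recovery summary; grids of 200–300 points back the
brute-force oracles. These sizes make every check a desk-scale computation
while leaving the estimators nothing to hide behind.

Known limitations: no hierarchical/Bayesian curve estimation, no
boundary-line or quantile-regression construction variants, no
spatial/remote-sensing NNI estimation, and single-variable economics only.
The classification step inherits the low power of small-block field
designs; with noisy data and close rates, plateau membership can flip
between seeds, which propagates into critical points — visible in the
spread of the noisy recovery errors.
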
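---
title: "Methods: mixture-design optimization of an enzyme-inhibiting essential-oil blend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-design optimization of an enzyme-inhibiting essential-oil blend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoblend)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the numerical choices, what the synthetic-data
generator does and does not emulate, and the design decisions made where
more than one defensible convention exists.

## The problem

Three essential oils — rose geranium (*Pelargonium graveolens*, x₁), false
yellowhead (*Inula viscosa*, x₂), lemongrass (*Cymbopogon citratus*, x₃) —
are blended in proportions summing to one, and each blend's inhibitory
potency against pancreatic α-amylase and intestinal α-glucosidase is
measured as an IC50 (mg/mL; lower is better). The question is which blend
minimizes each IC50, and whether blending is synergistic, i.e. beats the
best pure oil.

## Dose–response and IC50

Inhibition is the relative drop in assay absorbance,
`100·(A_control − A_sample)/A_control`. Values below 0% (apparent
activation) or above 100% are *retained* and only flagged, so the raw assay
arithmetic is never distorted; clipping would bias downstream IC50
estimates near the extremes of the tested range.

IC50 is located on the log10(concentration) scale, where these inhibition
curves are approximately linear across the five assayed concentrations
(0.062–1 mg/mL). The default estimator interpolates linearly between the
two adjacent concentrations bracketing 50% — the numerical equivalent of
reading the crossing off a semi-log plot, and the closest match to
graphical practice. An ordinary-least-squares variant (inhibition on
log10 concentration, solved for 50%) is selectable and is also the
fallback, flagged `extrapolated`, when no bracket exists. The log base is
irrelevant to the estimate (any base gives the same crossing); base 10 is
used for axis conventions. Replicate curves are estimated separately and
summarized as mean ± SD, matching how response tables report assay
replicates; a pooled-curve option averages inhibition per concentration
first. Four-parameter logistic fitting is deliberately out of scope: with
five points per curve and near-linear behaviour on the log scale, the
two extra shape parameters are not identifiable in any stable way.

## The design

`simplex_centroid_design()` builds the augmented simplex-centroid layout:
3 vertices (pure oils), 3 edge midpoints (50/50 binaries), the centroid,
and 3 axial points. Two conventions needed fixing:

* **Centroid replication.** The design is described with "two replications
  at the centroid" while the response table lists three identical centroid
  rows; the parameter `centroid_runs` therefore counts *total* centroid
  rows and defaults to 3 (1 point + 2 replicates). These replicates are the
  only source of pure error in the default design.
* **Axial fraction.** The axial compositions are the (2/3, 1/6, 1/6)
  permutations, inferred from their printed 3-decimal renderings
  (0.667/0.167/0.167); the fraction is exposed as `axial_fraction` since
  other choices (e.g. midway to each vertex at different depths) exist.

Proportions are built from exact fractions so every run sums to one at
machine precision; 0.333/0.667 are display renderings only. The packaged
response table restores the exact fractions on load for the same reason —
fitting on the rounded values would perturb coefficients in the third
decimal and break exact replicate detection. Run order is canonical by
default; `randomize_runs()` provides the seeded randomization used when
executing such designs in the lab.

## The Scheffé special-cubic fit

With proportions summing to one, the constant term is absorbed into the
linear terms, so the model is fitted *without intercept* on the seven
regressors (x₁, x₂, x₃, x₁x₂, x₁x₃, x₂x₃, x₁x₂x₃). The fit is ordinary
least squares via QR; standard errors use the unbiased residual variance on
n − 7 degrees of freedom and the inverse cross-product matrix; coefficient
p-values are two-sided Student-t. No multiple-testing correction is applied
across the seven terms, matching reporting practice for these designs.

Two conventions matter and are worth stating explicitly:

* **Corrected total sum of squares.** Although the model has no intercept,
  the ANOVA uses the *corrected* total `Σ(y − ȳ)²` on n − 1 df with
  regression on 6 df (seven terms minus the one absorbed by the mixture
  constraint). This is the convention of mixture-design software, and it is
  the only convention under which the published ANOVA table (total df 11)
  reproduces. R's `summary.lm` would report the uncentred R² for a
  no-intercept model, which is why `glance()` computes R² itself.
* **Lack of fit / pure error.** Pure error is the within-group sum of
  squares over *exact duplicate compositions* (the centroid triplicate
  here, 2 df); lack of fit is the residual remainder. `F_LOF =
  MS_LOF/MS_PE` tests model adequacy against replicate noise. When a design
  has no replicates the split is omitted with a warning rather than
  silently reporting a meaningless zero-df pure error.

Fitting the packaged 12-run table reproduces the published coefficient
tables to three decimals and the published lack-of-fit F for α-glucosidase
(3.8582) exactly. Note that recomputing that F from the published ANOVA
table's own *rounded* SS cells gives ≈ 3.33 — the printed statistic comes
from full-precision data, which is what this package uses; the value is
always reported as computed.

`reduce_scheffe()` optionally refits after dropping interaction terms with
p > 0.05 (never linear terms, which a Scheffé polynomial requires). One
caution: the published *reduced* α-amylase equation simply deletes the two
non-significant terms from the full fit while keeping the remaining
estimates unchanged. That is a truncation, not a refit; a genuine refit
shifts the retained coefficients (e.g. the ternary term moves from 3.110
to ≈ 3.19). The package keeps proper refit semantics and leaves the
truncated form to `coefficient_table()` plus manual term selection.

## Optimization and desirability

`optimize_blend()` minimizes a fitted (or published) surface by exhaustive
evaluation on a simplex lattice of pitch 0.001 — compositions are reported
to 2–3 decimals, so the lattice resolves every reportable blend — followed
by deterministic pairwise coordinate descent from the best node, with step
halving down to 1e-6. A special cubic on a compact simplex is a smooth
low-order polynomial, so the dense grid brackets the global minimum and the
polish refines it; ties break toward the lexicographically smallest
composition so results are reproducible to the bit. For both published
blend models the optimum lies on a boundary edge (one oil absent), which
the `boundary` column makes explicit.

Desirability uses the Derringer minimize ramp: 1 at or below the target T,
0 at or above the bound U, linear (weight 1) in between; multi-response
scores combine by geometric mean. The study this package reimplements never
states its T and U, so the defaults are T = the minimum found and U = the
largest observed response — under which the optimum scores 1.0 by
construction. The published "99%" desirability therefore reflects
undocumented software bounds and is not a target the package tries to hit.
A joint two-enzyme compromise optimum can be formed with
`overall_desirability()`, but the reported optima are per-response.

## Reactivity descriptors and retention indices

From HOMO/LUMO energies (eV), the conceptual-DFT global descriptors follow
Koopmans-type identities: IP = −E_HOMO, EA = −E_LUMO, gap = E_LUMO −
E_HOMO = IP − EA, χ = (IP + EA)/2, η = gap/2, μ = −χ, ΔN_max = −μ/η. These
are pure arithmetic downstream of the orbital energies; the
electronic-structure calculation itself is out of scope. A zero gap makes
η = 0 and ΔN_max undefined, which is an error rather than an Inf. All five
packaged metabolites reproduce their published descriptor rows to three
decimals from the two energies alone — an internal-consistency check of
both the table and the arithmetic. The packaged label "b-mercene" is kept
verbatim (almost certainly β-myrcene) so the golden fixture stays faithful
to its source.

Kovats retention indices default to the temperature-programmed *linear*
form, RI = 100·(n + (N − n)(t − tₙ)/(t_N − tₙ)), appropriate for a linear
GC ramp; the classical isothermal logarithmic form is available via
`method = "isothermal"`. Peaks outside the alkane ladder are refused rather
than extrapolated.

## The synthetic-data generator

`simulate_mixture_responses()` emulates the response table's structure: the
special-cubic surface evaluated at each design point, three replicate draws
with additive Gaussian noise, reported as mean ± SD. Defaults are the study
conditions: the 12-run design, 3 assay replicates, and noise SD 0.003
mg/mL — the centre of the 0.001–0.009 mg/mL range of the measured
replicate SDs. Additive Gaussian noise matches the symmetric ± reporting;
a log-normal option keeps simulated IC50s positive when exploring noise
levels far above the assay's. `simulate_dose_response()` generates the
five-concentration curves from the exact log-linear law with a known IC50.

What the generator does *not* emulate: heteroscedastic assay noise (the
measured SDs vary by run; the generator draws i.i.d. noise), plate/batch
effects, correlation between the two enzyme responses, and any curvature of
real dose–response curves beyond log-linearity. Passing parameter-recovery
tests therefore demonstrates correctness of the estimators under the
model's own assumptions, not robustness to real-assay pathologies.

`parameter_recovery()` refits across simulations and reports bias, RMSE and
empirical vs analytic SEs (σ²(XᵀX)⁻¹ with σ = noise_sd/√replicates, since
each fitted response is a replicate mean). At the default noise level the
linear-coefficient bias is indistinguishable from zero and empirical SEs
sit within a few percent of analytic — OLS behaving as OLS should on this
design. Reproducibility uses R's default RNG under `withr::with_seed`; a
fixed seed gives byte-identical simulation output.

## Problem sizes and determinism

Everything here runs in seconds on one core: the design has 12 runs, fits
are 12×7 least squares, the default optimizer lattice has 501,501 nodes
evaluated vectorized, and the recovery studies in the test suite use
150–500 simulations. All randomness flows through explicit seeds; every
deterministic path (fits, ANOVA, optimizer, descriptors) is bit-reproducible
across runs.

## Known limitations

* The special cubic cannot represent asymmetric edge effects beyond a
  single product term per edge; with 12 runs and 5 residual df, that is the
  richest polynomial this design supports.
* Assay SDs are carried through reporting but are not used as weights in
  the fit (the published analysis is unweighted OLS; a weighted variant
  would change the ANOVA conventions).
* The desirability bounds are study-level choices; comparisons of
  desirability values across studies are not meaningful.
* IC50 interpolation assumes a monotone-enough curve near 50%; strongly
  non-monotone curves fall back to regression and are flagged.
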
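---
title: "Methods: gradient arithmetic and hit-counting assignment in nafkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient arithmetic and hit-counting assignment in nafkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafkit)
```

## The problem

Non-aqueous fractionation (NAF) separates freeze-dried, finely ground plant
material in a water-free density gradient. Organelle fragments band at
characteristic densities, but never cleanly: every gradient fraction is a
mixture of compartments. The experiment therefore measures, per fraction,
(a) the activities of three compartment-specific marker enzymes — alkaline
pyrophosphatase (plastid), UGPase (cytosol), acid phosphatase (vacuole) —
and (b) metabolite abundances (GC-MS peak areas). A metabolite's
subcellular distribution is inferred from how closely its profile follows
each marker's profile. `nafkit` implements the two computational stages:
the solvent arithmetic that realizes the gradient at the bench, and the
correlation algorithm that turns profiles into per-compartment percentages.

## Gradient arithmetic

An ideal binary mixture of heptane (7H, ρ = 0.68 g cm⁻³) and
tetrachlorethylene (TCE) has density ρ = Σρᵢ·Vᵢ / ΣVᵢ (volume additivity
assumed; no excess-volume correction, no temperature dependence).
`diluent_volume_for_target()` inverts this for the diluent volume, and
`plan_gradient()` chains it down the supernatant loop, tracking cumulative
volumes and verifying each step by recomputing the mixture density:

```{r gradient}
plan_gradient(1.05, 1.55, targets = c(1.45, 1.40, 1.35))
```

The TCE density constant is 1.60 g cm⁻³: it is the unique value consistent
with the heptane density and the 0.484:1 7H:TCE ratio that defines the
1.3 g cm⁻³ suspension mixture. Tabulated literature values at 20–25 °C
(≈1.62) reproduce neither anchor; the constant is configurable via
`solvent("tetrachlorethylene", density = ...)`, and this back-inference is
a package choice, not a claim about any particular batch of solvent.
Internal arithmetic is full precision; rounding to pipettable microlitre
precision is presentation only.

## The assignment algorithm

Profiles are first percent-normalized per sample: detected values are
scaled to sum to 100 (`normalize_profile()`). Missing metabolite values
(empty cells) mean "not detected" and are excluded from normalization and
pair building; marker profiles must be complete.

For `f` fractions and each pair *i* < *j* the **slope** is the
percentage-point difference Δᵢⱼ = %ⱼ − %ᵢ — `choose(f, 2)` slopes per
analyte. The slope is deliberately *not* divided by the density spacing:
the distance below subtracts slopes of identically indexed pairs, so any
common denominator cancels; a density-normalized variant is available
(`slope_mode = "density-normalized"`) for sensitivity analysis. The
**distance** of metabolite x to compartment C on a pair is
Ψ = |Δᵢⱼ(Metₓ) − Δᵢⱼ(C)|.

Per pair, the minimum Ψ marks the closest compartment, and each of the
uncertainty **bounds** b ∈ {5, 7.5, 10} percentage points awards one
**hit** to every compartment with Ψ − min Ψ < b (strict inequality, as the
rule is stated; boundary-equal differences do not hit). The graded bounds
distinguish near-ties from clear calls: the arg-min compartment always
earns 3 hits, a compartment 6 points away earns 2, one 20 points away
earns 0. The bounds represent the typical technical error of photometric
enzyme assays and GC-MS quantification and are configurable
(`algorithm_config(bounds = ...)`).

Two schemes are implemented because the counting of the minimum itself
admits two readings:

* **bound-loop** (default): the minimum is counted *through* the bound
  loop — the arg-min satisfies every bound, so it earns `length(bounds)`
  hits, and compartments tied at the minimum earn the same. A full
  three-way tie yields 33.33/33.33/33.33. This is the reading consistent
  with observed full-tie outputs of equal thirds with zero replicate SD
  (e.g. a metabolite whose markers are indistinguishable).
* **min-plus-bounds**: one additional separate hit for the arg-min (first
  in label order on ties). A full tie then yields 40/30/30 — the asymmetry
  is why this scheme is not the default; it is kept for sensitivity
  analysis.

**Single-fraction special case.** A metabolite detected in exactly one
fraction admits no pairs; the compartment with the highest marker percent
in that fraction receives the full weight (default 3 = `length(bounds)`,
so the case carries the same weight as a unanimous pair). Ties at the
maximum follow `tie_policy` (`all-pass` default, or `split`); the two
policies give identical *relative* distributions since hits are
renormalized.

Metabolites detected in 2 ≤ k < f fractions build pairs over the detected
fractions only, matched against marker slopes on those same pairs — the
distance requires matched pair indices, and this is the minimal extension
of the stated rules to partial detection.

Summed hits are normalized to percents (exact ratios internally; one
decimal at presentation), replicates are aggregated as arithmetic mean ±
sample SD (n − 1; with a single replicate the SD is reported as 0 and
flagged), and absolute per-compartment levels are the product of the mean
relative distribution with the whole-tissue level, with SDs propagated in
quadrature: SD = level·√((SD_rel/mean_rel)² + (SD_whole/mean_whole)²).
Per-replicate products would be an alternative pairing; the product of
means with propagation was chosen because whole-tissue replicates come
from different physical samples than the fractionated ones, so no natural
replicate pairing exists.

```{r assignment}
markers <- marker_profiles(plastid = c(60, 25, 10, 5),
                           cytosol = c(15, 50, 25, 10),
                           vacuole = c(5, 10, 25, 60))
metabolite_distribution(normalize_profile(c(30, 26, 22, 22), "met"), markers)
```

## Condition statistics and clustering

Condition comparisons per metabolite and compartment use one-way ANOVA on
the per-replicate percents (`stats::aov`); with more than two conditions,
Tukey HSD pairwise p-values are appended. Stars are a pure threshold map
(p < 0.05/0.01/0.001) and arrows follow the sign of the later condition's
mean minus the earlier one's; arrows are shown only for significant
shifts. No family-wise correction is applied across metabolites — each
metabolite/compartment cell is annotated independently, matching the
tabular reporting convention for this assay. When all groups are constant,
the F statistic is undefined; the package reports p = 1 for equal means
(and p = 0 for separated constant groups) rather than NaN.

For the clustering view, condition-mean distributions are z-scored per row
(sample SD denominator, n − 1, matching the replicate-SD convention;
population denominator available; constant rows are dropped with a
warning, never silently), then clustered on Euclidean distances with
average linkage by default. The linkage was an open choice —
single/complete/Ward are one argument away — and average linkage was
chosen as the common default for profile heatmaps with monotone merge
heights. Leaf order follows `stats::hclust` tie-breaking and is documented
as order-dependent only up to ties. Outlier screening is available only as
an explicit, default-off IQR fence upstream of the user; the package never
removes data silently.

## The synthetic generator

`generate_experiment()` emulates the study conditions end to end, with
known ground truth:

* **Marker shapes**: discretized overlapping Gaussian curves over the
  fraction axis, normalized to 100 — plastid banding light (peak at 0.15
  of the axis), cytosol intermediate (0.5), vacuole dense (0.9), widths
  ≈0.2. This mirrors the characteristic ordered enrichment of real
  gradients rather than arbitrary simplex draws; identical shapes are
  allowed and flagged as the degenerate full-tie regime.
* **Metabolites**: convex mixtures Σ w꜀·marker꜀ with weights drawn
  uniformly on the simplex — the premise of the method is precisely that
  fraction contents are compartment mixtures.
* **Noise**: i.i.d. multiplicative lognormal noise on raw abundances,
  mean 1, default CV 0.05. Multiplicative lognormal because peak areas
  and activities are positive and heteroscedastic; 5% is a realistic
  technical CV for photometry/GC-MS and matches the scale of the
  algorithm's uncertainty bounds. No quantitative error figures are
  published for this assay, so the default is a stand-in, exposed in
  `synthetic_config(noise_cv = )`.
* **Layout**: `f = 6` fractions over densities 1.30–1.55 g cm⁻³, 3
  replicates, optionally two conditions with independently drawn weights;
  whole-tissue levels are generated alongside. A single master seed
  derives per-stream sub-seeds (weights, whole-tissue, noise), so every
  run is reproducible bit for bit.

What the generator does **not** emulate: cross-contamination beyond
profile overlap, fraction-to-fraction correlation of technical error,
missingness mechanisms (detection limits), drift between batches, or any
physics of the fractionation itself. Passing recovery tests therefore
demonstrates that the estimator inverts its own generative premise under
realistic noise — not that it is unbiased on real tissue, where marker
profiles carry their own measurement error structure.

## Numerical and testing choices

Percent profiles must sum to 100 within 1e-9 over detected fractions, and
every relative (absolute) distribution is checked to conserve 100 (the
whole-tissue mean). Hit counting is exact integer/rational arithmetic;
ties are exact floating-point equalities, which is appropriate because
tied Ψ values arise from identical inputs, not from rounding. The test
suite verifies the engine against an independent brute-force loop
implementation on hundreds of randomized instances (f ∈ 3..6, random
detection masks), checks bound monotonicity and compartment-permutation
symmetry, and validates the noise model by Monte-Carlo. The
parameter-recovery simulation uses 200 metabolites, 3 replicates, f = 6
and CV 0.05 — sizes chosen to exercise the full pipeline in seconds while
estimating the dominant-compartment recovery rate with a few-percent
standard error; the pass threshold (≥80% recovery for metabolites with a
dominant weight ≥0.6) is stored in the test configuration as a verified
property of the estimator.

## Known limitations

* Only the three-compartment marker set is resolved; mitochondria and
  peroxisomes band too close to separate with this gradient and are out
  of scope, as is any least-squares deconvolution estimator.
* Hit counting estimates similarity, not the mixture inverse: strongly
  mixed metabolites are pulled toward equal thirds (visible in the
  README's worked example), so relative distributions near 33/33/33 are
  ambiguous between genuine mixing and marker indistinguishability — the
  replicate SD and the marker separation must be inspected together.
* Blank correction of enzyme activities is assumed done upstream; the
  package accepts already-reduced activities.
* The gradient arithmetic assumes ideal volume additivity of the two
  solvents.
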
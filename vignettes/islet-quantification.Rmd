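---
title: "Quantifying the pancreatic islet microenvironment from immunostained sections"
author: "isletquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pancreatic islet microenvironment from immunostained sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletquant)
```

## The measurement problem

In feline diabetes mellitus, as in human type-2 diabetes, the endocrine
pancreas deteriorates in stages: insulin expression per beta cell can fall
before beta cells disappear, and beta cells can disappear before whole
islets are lost. Distinguishing these stages on archival tissue requires
three read-outs per animal:

1. **Islet area fraction** — the synaptophysin-positive area as a
   percentage of the whole pancreatic tissue examined. Synaptophysin
   labels all islet endocrine cell types, so its stained area proxies
   total islet mass independently of insulin content.
2. **Insulin-positive fraction of islet area** — the percentage of each
   islet occupied by beta cells, from immunofluorescence for insulin
   within the synaptophysin-delineated islet regions.
3. **Insulin signal intensity** — the anti-insulin fluorescence
   integrated within the islet masks, a surrogate for insulin content of
   the remaining beta cells.

A cohort in which read-out 1 falls while 2 holds steady and 3 falls is
the signature of beta-cell exhaustion preceding islet loss.

`isletquant` implements this measurement chain end to end — segmentation,
quantification, per-animal aggregation, and the group statistics — plus a
synthetic-cohort generator with exact ground truth, because the archival
slides such studies run on are not publicly deposited. Every claim the
package makes about its own accuracy is established against that
generator by the test suite and `scripts/acceptance.R`; this vignette
states no number those runs do not themselves compute.

## Segmentation model

All spatial parameters are specified in micrometres and converted through
the image's pixel size, so one configuration transfers across
magnifications.

**Tissue.** The channel sum is Gaussian-blurred (`blur_sigma`, default
1 µm) and thresholded, by default with the triangle method: the histogram
of a slide scan is a sharp bare-glass peak plus a broad tissue hump, the
shape the triangle construction assumes. Two numerical details matter.
First, the histogram is built after clipping the top 1% of blurred
values: the sparse, very bright islet and nuclear pixels would otherwise
stretch the histogram range and drag the triangle's far anchor — and
with it the threshold — into the empty tail. Second, holes are filled
and components below `min_tissue_area` (default 10 000 µm²) dropped. An
empty result raises an explicit `isletquant_no_tissue` condition; the
pipeline excludes such images and logs them rather than emitting silent
zeros. This is the behaviour at the sensitivity limit: when tissue
autofluorescence sits at the shot-noise floor (background ≲ 2 photon-sd
on an 8-bit scale) tissue genuinely cannot be told from glass, and an
explicit exclusion is the only honest output.

**Islets.** The synaptophysin channel is thresholded by Otsu's method
computed *within tissue pixels only*, so bare glass cannot bias the
threshold. Otsu always produces a split, even of a pure background
histogram, so a guard decides whether the split is real: the separation
`(mean(foreground) − mean(background)) / sd(background)` must exceed
`min_class_separation` (default 5). A split carved out of a single
background mode scores ~2–3 regardless of class proportions, while
genuine marker signal sits tens of background-sds above the
autofluorescence; unlike Otsu's between-to-total variance ratio, this
statistic does not degrade when islets occupy only ~0.3% of the tissue.
Fields that fail the guard read 0% islet area — a valid result, not an
error. The thresholded mask is closed (`closing_radius`, 2 µm),
hole-filled, filtered at `min_islet_area` (300 µm², rejecting single
stray positive cells — islets are multicellular), and intersected with
the tissue mask. Islets touching the frame border are kept by default
(`exclude_border_islets` reverses this).

**Insulin-positive area.** The insulin channel is Otsu-thresholded using
only islet pixels, with the same separation guard, and the result
intersected with the islet mask. Because the threshold depends only on
islet pixels, randomising everything outside the islet mask leaves the
result bit-identical (a property the tests assert).

The construction gives the nesting invariant
`insulin_positive ⊆ islet ⊆ tissue` by composition, and fixed-threshold
variants are monotone: raising a threshold can only shrink a mask
(closing, hole-filling, and area filters all preserve the subset
relation).

**Brightfield route.** Double-stained IHC tiles (haematoxylin
counterstain, brown DAB for synaptophysin, magenta AP) are unmixed by
standard colour deconvolution: per-channel optical density
`OD = −log10((I + 1)/256)`, then the inverse of a unit-norm stain
matrix. The default matrix uses the published haematoxylin and DAB
vectors and a fast-red-type vector for the AP chromogen; real kits vary,
so it is user-replaceable. The synthetic IHC renderer composes
transmitted RGB as the *exact* Beer–Lambert inverse of that transform,
`I = 256·10^(−OD) − 1`, so the noise-free render/deconvolve round trip
is lossless in floating point (machine-precision agreement; 8-bit PNG
quantisation, not the mathematics, is what limits a round trip through
files). The DAB-positive mask is a fixed OD threshold (default 0.3)
within tissue followed by the islet-mask cleanup.

## Quantification and aggregation

Per image: tissue and islet areas (µm²), islet area as % of tissue,
insulin-positive area as % of islet, and the insulin intensity
statistics — integrated (sum over islet pixels), mean per islet pixel,
and the background level (median insulin intensity over tissue outside
islets), with background-subtracted variants. The identity
`integrated = mean × pixel count` is asserted at construction.

Per animal, images are combined by tissue-area-weighted means (an
unweighted option exists): a field that sampled more tissue carries
proportionally more evidence. Animals whose every field lacked
detectable islets keep their (zero) area read-out but carry missing
intensity values and are excluded from intensity comparisons with a
warning — exclusion with logging, never imputation.

The *primary* intensity statistic for group comparison is the
background-subtracted mean intensity per islet pixel: integrated
intensity confounds islet size with insulin content, and islet size is
already measured by the area metric. The raw integrated value is still
computed and reported, since integrating within the islet masks is how
the read-out is classically described; whether background was subtracted
in prior work is typically unstated, so both forms are kept side by
side.

## Group statistics

Per metric the workflow is: log10 transform of the per-animal values;
Bartlett (variance homogeneity) and Shapiro–Wilk (normality) gates at
p > 0.05, which are *reported, never enforced* — a violated gate flags
the comparison but does not halt it; then a two-sided Dunnett
many-to-one test of each non-control group against the control at
α = 0.05, with raw-scale mean ± sd summaries per group.

The Dunnett test is the classical pooled-variance form, matching the
homogeneity gate: with groups `0 (control), 1, …, m`,
`s²` pools all within-group variances on `N − k` degrees of freedom,
`SE_j = √(s²(1/n_j + 1/n_0))`, `t_j = (x̄_j − x̄_0)/SE_j`, and the
two-sided adjusted p-value is `P(max_j |T_j| ≥ |t_j|)` under the
equicorrelated multivariate-t null with `ρ_ij = λ_i λ_j`,
`λ_j = √(n_j/(n_j + n_0))`. That probability is evaluated through the
factor representation `T_j = (λ_j Z₀ + √(1−λ_j²) Z_j)/S`,
`S = √(χ²_ν/ν)`, as a nested adaptive quadrature over `(Z₀, S)` with
relative tolerance 1e-10; beyond 8 comparisons a fixed-seed Monte-Carlo
evaluator (10⁶ draws) replaces the quadrature, where the product of m
normal-CDF differences makes quadrature increasingly ill-conditioned.
For `m = 1` the representation collapses algebraically to the central
t distribution, so the test reduces *exactly* (to quadrature tolerance,
≲1e-10) to the classical pooled two-sample two-sided t-test — the suite
checks agreement at 1e-8 over 50 datasets, and checks `m = 2` against
both a 10⁶-draw Monte-Carlo oracle and an independent multivariate-t
implementation.

Zero-valued metrics (an animal with no detected islets has 0% islet
area) make log10 undefined. The default policy is an error naming the
animal; documented alternatives are exclusion (used by the pipeline
driver, with a warning) or a fixed offset, each recorded in the result.
No multiplicity correction is applied across the three metrics,
matching the single-comparison-per-metric design.

## The synthetic cohort generator

The generator is the package's reference instrument, so its defaults are
the study conditions rather than free dials:

| Parameter | Default | Rationale |
|---|---|---|
| frame | 2048 × 2048 px at 0.25 µm/px | ~0.26 mm² field, plausible ×40 scan; tests and the acceptance script use 512 px at 1 µm (identical physical field, coarser raster) to run in minutes |
| islet area target | 0.8% control / 0.3% diabetic | the two published group means |
| insulin-positive fraction | 0.55 control / 0.47 diabetic, per-animal sd 0.11 / 0.21 | published means ± sd |
| diabetic insulin intensity | 0.5 × control | the glucotoxic intensity contrast the pipeline must recover |
| cohort | 10 control vs 9 diabetic | the study's animal counts |
| between-animal islet-fraction spread | ×10^N(0, 0.25) | log10-scale sd 0.25, the spread that makes the published group contrast detectable at the published n with power ≈ 0.93 |
| intensity jitter | ×10^N(0, 0.05) | mild technical/biological variation |
| islet radii | lognormal, median 40 µm, log-sd 0.5, floor 12.5 µm | islet size range; the floor (~490 µm²) keeps every generated islet above the segmentation size filter |
| noise | Poisson gain 1, Gaussian sd 2 (8-bit) | shot + read noise at which default segmentation still achieves IoU ≥ 0.9 |
| background | level 10, smooth lognormal texture (log-sd 0.2) | autofluorescence with the broad structured histogram real tissue shows; bare glass stays a sharp peak |

Geometry: a smooth harmonic-perturbed tissue blob (≥60% of the frame);
non-overlapping area-preserving ellipses (axis ratio 1–2, random
orientation) placed inside it. Radii are drawn from the lognormal
*truncated to the remaining area budget*, so placement never overshoots
and never stalls; when the remaining deficit falls below one
minimum-size islet the last islet is swapped for one that exhausts the
deficit exactly, landing the achieved fraction on the target to within
rasterisation error — well inside the ±10% band the generator
guarantees. A target smaller than one minimum islet (common for
down-jittered diabetic animals at desk-scale frames) is rounded
stochastically to zero or one islet with the unbiased probability, which
is also what sparse diabetic fields look like. Geometrically impossible
requests fail with an explicit error naming achieved vs requested
fraction. The beta-cell subset grows as one connected blob per islet
from a random interior seed (beta cells cluster in islet cores); an
independent-Bernoulli alternative is a config option.

Seeds: every per-animal and per-image stream is derived from the master
seed by hashing the label path (group, animal index, image index), so
adding a group or animal never perturbs previously generated data, and
identical spec + seed reproduces every output byte for byte.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real slides: out-of-focus light and
chromatic shift, uneven illumination and stitching seams, partial-volume
staining gradients within islets, amyloid deposits, vasculature,
exocrine autofluorescence structure beyond the smooth texture field,
section folds and tears. Accuracy numbers here are upper bounds for
well-behaved real data, not guarantees.

## Calibration of the statistics

The type-I-error and power properties are established at the metric
level with `simulate_cohort_metrics()` — per-animal read-outs drawn from
the lognormal measurement model the image pipeline produces — because
these are properties of the per-animal distribution, not of pixels: 200
null cohorts give an empirical type-I error inside [0.02, 0.10] at
nominal 0.05, and 100 cohorts at the 0.8% vs 0.3% effect with n = 10 vs
9 give power ≥ 0.9 (the analytic value at these settings is ≈ 0.93).
The pixel-level chain is exercised separately by the ground-truth
recovery and intensity-contrast checks.

## Problem sizes and numerical choices

The test suite and acceptance script use 512-px (accuracy checks) and
256-px (invariant sweeps, determinism) frames at pixel sizes keeping the
physical field at ~0.26 mm², 20-image recovery sets, 100-field invariant
sweeps, 200 + 100 calibration cohorts, and 10⁶-draw Monte-Carlo oracles
— sizes chosen so the whole validation runs in a few minutes on one
core while keeping every Monte-Carlo standard error far below the
tolerance it supports. Degenerate inputs are handled explicitly
throughout: empty masks flag rather than zero, constant histograms
return infinite thresholds (empty masks), identical groups give Bartlett
p = 1 and Dunnett p = 1, zero pooled variance is an error, and negative
unmixed optical densities clip at zero.

## Repository shape

The package is organised as an analysis workflow: the numbered drivers
under `analysis/` (simulate → segment/quantify → compare → calibrate)
narrate the study over the package functions in `R/`, writing their
tables under `results/`; the same functions back the test suite and
`scripts/acceptance.R`. There is no shell CLI — the functions and
drivers are the interface, which fits a study pipeline better than a
deployable tool.

## Known limitations

- Automated thresholding stands in for whatever combination of manual
  annotation and vendor software produced the original slide
  measurements; no fidelity to that procedure is claimed, only to the
  defined read-outs.
- The per-image field count and field-selection rules of the original
  study are unstated; `images_per_animal` is exposed with no claim about
  the study's value.
- Nucleus-level segmentation, per-cell counting, colocalisation,
  object-level islet statistics beyond the size filter, 3D stacks, and
  whole-slide tiling are out of scope.
- At very low autofluorescence (≲2 photon-sd) tissue detection fails
  explicitly; about 2% of fields in the randomized invariant sweep hit
  this regime and are excluded by the documented error path.
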
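# isletquant

Quantification of the pancreatic islet microenvironment from
immunostained tissue sections, for studies comparing diabetic and
non-diabetic cohorts (the motivating system is feline diabetes mellitus,
a natural model of human type-2 diabetes).

From multichannel immunofluorescence fields (DAPI nuclear counterstain,
synaptophysin as the pan-endocrine islet marker, insulin for beta cells)
and colour-deconvolved brightfield IHC tiles (haematoxylin / DAB / AP),
the package measures, per image and per animal:

- **islet area** — synaptophysin-positive area as a percentage of the
  pancreatic tissue examined (a surrogate for islet mass),
- **insulin-positive fraction** — the percentage of islet area occupied
  by beta cells,
- **insulin intensity** — the anti-insulin fluorescence integrated
  within the synaptophysin-delineated islet masks, raw and
  background-subtracted.

Group comparison follows the classical workflow for such cohorts: log10
transform of per-animal values, Bartlett and Shapiro–Wilk assumption
gates (reported, not enforced), and a two-sided Dunnett many-to-one test
against the control group at α = 0.05. The Dunnett p-value is computed
in-package from the equicorrelated multivariate-t null via its factor
representation,

    T_j = (λ_j Z0 + sqrt(1 − λ_j²) Z_j) / S,   λ_j = sqrt(n_j / (n_j + n_0)),

with `p = P(max_j |T_j| ≥ |t_obs|)` evaluated by nested adaptive
quadrature; for one comparison it reduces exactly to the pooled
two-sample t-test.

Because studies of this kind run on archival slides that are not
deposited, the package ships a synthetic-cohort generator with exact
ground truth (islet geometry, beta-cell masks, intensities, shot + read
noise, brightfield Beer–Lambert rendering) whose defaults encode the
study conditions: 10 control vs 9 diabetic animals, islets at 0.8% vs
0.3% of tissue area, 55% vs 47% insulin-positive islet area, and halved
diabetic insulin intensity. All accuracy and calibration claims are
established against this generator by the test suite.

## Worked example

The numbered drivers under `analysis/` run the whole study at desk
scale (512-px fields, ~0.26 mm² each; images under `scratch/`, tables
under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_segment_quantify.R
Rscript analysis/03_group_stats.R
Rscript analysis/04_calibration.R
```

Step 3 prints, for the simulated cohort (seed 20260924):

```
Group comparison: islet_area_pct_of_tissue (log10 scale, control = non_diabetic)
  non_diabetic   n=10  mean 1.037 +/- 0.5712 (raw scale)
  diabetic       n= 9  mean 0.2804 +/- 0.09903 (raw scale)
  Bartlett p = 0.2313; Shapiro-Wilk p = non_diabetic 0.3599, diabetic 0.0683; gates passed
  diabetic - control: diff=-0.5277 SE=0.1042 t=-5.062 df=17 p=0.0001 *
...
Findings at alpha = 0.05:
  islet_area_pct_of_tissue         t = -5.062, p = 0.0001 -> group difference detected
  insulin_pos_area_pct_of_islet    t = -0.438, p = 0.6672 -> no difference detected
  insulin_mean_intensity_bgsub     t = -4.964, p = 0.0001 -> group difference detected
  insulin_integrated_intensity     t = -7.559, p = 0.0000 -> group difference detected
```

Read-out: the diabetic group shows a reduced islet area fraction
(0.28% vs 1.04% of tissue; `diff` is the difference of group means on
the log10 scale) and reduced insulin intensity within its remaining
islets, while the insulin-positive *fraction* of islet area does not
differ — the pattern of falling insulin expression preceding beta-cell
loss. Step 4 reports the calibration of the statistical chain
(empirical type-I error 0.020 over 200 null cohorts at nominal 0.05;
power 0.97 over 100 cohorts at the 0.8% vs 0.3% effect).

The same machinery is available programmatically:

```r
library(isletquant)
p   <- generator_params(image_shape = c(512L, 512L), pixel_size = 1)
gt  <- sample_islet_geometry(p)        # ground-truth masks + fractions
img <- render_if_image(gt, p)          # 3-channel field with sensor noise
m   <- per_image_metrics(img, segment_image(img))
m$islet_area_pct_of_tissue             # 0.7527 (ground truth: 0.7613)
```

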
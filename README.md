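# legquant

Quantitative 3D MRI volumetry and soft-tissue composition analysis of the
lower leg, built for studies of clubfoot (congenital talipes equinovarus,
CTEV) and other conditions with contralateral limb asymmetry.

On T1-weighted MR images the lower-leg tissues separate by intensity
(subcutaneous fat bright, muscle intermediate, cortical bone dark), so
anatomy can be quantified by segmenting the volume and counting voxels.
`legquant` implements the full analysis:

* **Segmentation** — multi-level Otsu (or fixed) intensity thresholding,
  connectivity-based resolution of background vs cortical bone and of the
  subcutaneous fat shell vs intramuscular fat, morphological cleanup, and
  tibia/fibula identification by component size; plus subtraction MR
  angiography (systole − diastole, robust-SD thresholding) for arteries.
* **Volumetry and composition** — per-leg volumes V_Leg, V_Musc, V_Fat,
  V_Tibia, V_Fibula in cm³, and soft-tissue percentages
  `Muscle% = 100·V_Musc/(V_Musc+V_Fat)` (likewise `Fat%`).
* **Intramuscular fat** — `TA_Musc`, the percentage of muscle voxels whose
  intensity exceeds 1.5× the median of neighbouring muscle voxels
  (in-plane window, radius 5), a proxy for intra-/inter-muscular adipose
  tissue.
* **Statistics** — contralateral ratios (affected:unaffected or
  right:left), mean ± SD summaries, an exact two-sample
  Kolmogorov–Smirnov test (lattice-path enumeration, tie-aware, validated
  against brute force) suited to very small samples, and the FEM
  (cross-operator coefficient of variation) reproducibility metric.
* **Synthetic phantoms** — seeded, analytically volume-controlled 3D leg
  phantoms (elliptic-cylinder geometry, Michelson-contrast intensities,
  per-class Gaussian noise at configurable SNR, planted intramuscular-fat
  speckles, systole/diastole pairs) with ground-truth label maps, used to
  validate every stage end to end.

The package ships a fixture table (`load_paper_fixture()`) with the
published per-leg measurements of an 11-participant CTEV cohort study
(5 controls, 4 unilateral, 2 bilateral), so the full statistical analysis
is reproducible from the printed values.

## Worked example

```r
library(legquant)

report <- run_pipeline(load_paper_fixture())
report
#> <cohort_report> 22 legs, 11 participants
#>   contrast V_Leg_ratio    D = 1, p = 0.01587
#>   contrast V_Musc_ratio   D = 1, p = 0.01587
#>   contrast V_Fat_ratio    D = 0.6, p = 0.2857
#>   contrast V_Tibia_ratio  D = 1, p = 0.01587
#>   contrast V_Fibula_ratio D = 1, p = 0.01587
#>   contrast muscle_pct     D = 0.8, p = 0.008991
#>   contrast ta_musc        D = 1, p = 0.0002498
```

Every contrast compares controls with affected legs: the unilateral
affected:unaffected volume ratios separate completely from the control
right:left ratios for leg, muscle, tibia and fibula (D = 1 — every affected
leg is proportionally smaller than any control asymmetry), but not for
subcutaneous fat (D = 0.6). The muscle share of soft tissue
(`muscle_pct`, control legs vs one value per affected participant) and the
intramuscular-fat statistic (`ta_musc`) are likewise strongly separated.

```r
s <- report$summaries
s$unilateral_V_Musc_ratio
#> n = 4, mean +/- SD = 0.5951 +/- 0.0775, IQR [0.5837, 0.6366], median 0.6251
s$control_muscle_pct
#> n = 10, mean +/- SD = 59.99 +/- 6.544, IQR [55.39, 64.09], median 62.35
```

Affected legs carry on average 60% of the contralateral muscle volume,
while muscle makes up ~60% of control soft tissue.

A synthetic end-to-end run with known ground truth:

```r
base <- phantom_spec(grid_shape = c(64, 64, 48), voxel_size = c(2, 2, 3),
                     leg_length_mm = 120,
                     target_volumes = c(muscle = 220, subcut_fat = 150,
                                        tibia = 48, fibula = 9))
recovery <- parameter_recovery(cohort_spec(n_unilateral = 4, n_control = 0,
                                           n_bilateral = 0, seed = 55),
                               base, n_replicates = 5)
recovery[, c("tissue", "mean_estimate", "mean_truth", "bias")]
#>       tissue mean_estimate mean_truth          bias
#> 1     muscle     0.6047516  0.6000645  0.0046871517
#> 2 subcut_fat     1.0625000  1.0611800  0.0013200221
#> 3      tibia     0.9205000  0.9206309 -0.0001308656
#> 4     fibula     0.8763158  0.8843044 -0.0079886397
```

The pipeline recovers the planted affected:unaffected effect multipliers
(muscle 0.60, fat 1.05, tibia 0.92, fibula 0.89) with |bias| well under
0.01 through generation, segmentation and volumetry.

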
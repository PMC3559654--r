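---
title: "Methods: quantitative lower-leg MRI volumetry with legquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lower-leg MRI volumetry with legquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Clubfoot (congenital talipes equinovarus, CTEV) alters the development of
the lower leg: affected legs carry less muscle, slightly smaller bones, and
more adipose tissue inside the muscle compartment. On T1-weighted MR images
these tissues separate cleanly by intensity — subcutaneous fat is bright,
muscle intermediate, cortical bone dark — so the anatomy can be quantified
by segmenting a 3D volume and counting voxels. `legquant` implements that
pipeline end to end: tissue segmentation, voxel volumetry, soft-tissue
composition, an intramuscular-fat statistic, contralateral ratio analysis
and exact small-sample group comparisons, plus a synthetic phantom
generator used to validate every stage against a known ground truth.

The per-leg quantities are:

* `V_Leg`, `V_Musc`, `V_Fat`, `V_Tibia`, `V_Fibula` — voxel-count volumes
  in cm³ (count × voxel volume). The whole-leg volume is measured over a
  configured axial slice range, muscle and subcutaneous fat over a slightly
  shorter range, and the bones over the full volume, mirroring the
  anatomical cropping conventions of clinical protocols that bound the leg
  by the tibial plateau and plafond.
* `Muscle%` and `Fat%` — a tissue's share of the combined soft tissue,
  `100·V_tissue/(V_Musc + V_Fat)`; the two always sum to 100.
* `TA_Musc` — the percentage of muscle voxels whose intensity exceeds 1.5×
  a local muscle reference; a proxy for intra-/inter-muscular adipose
  tissue.

Asymmetry is expressed as contralateral ratios: affected/unaffected for
unilateral cases, right/left for controls and bilateral cases. Group
contrasts compare control right:left ratios against unilateral
affected:unaffected ratios, and control legs against one value per affected
participant (bilateral participants contribute the mean of their two legs).

## Segmentation

The protocol this package emulates was semi-automated: intensity
thresholding plus manual painting. `legquant` replaces the manual step with
deterministic morphological cleanup so the pipeline is fully scriptable:

1. **Three-class thresholding.** Multi-level Otsu (exhaustive two-cut
   search on a 256-bin histogram) splits the volume into dark, mid and
   bright classes. The cuts are then refined to the midpoints of adjacent
   class means: the variance-optimal cut can sit arbitrarily close to a
   class mode when the histogram has wide empty gaps, and the equidistant
   boundary is far more robust to intensity perturbation (this is what
   keeps the inter-operator experiment below 4% variation). Fixed cut
   points are available via `segmentation_config(threshold_mode =
   "fixed")`.
2. **Dark-class resolution.** Dark voxels are background or cortical bone.
   Background reaches the in-plane image border; bone is enclosed by soft
   tissue *within every axial slice*. The resolution is therefore by 2D
   per-slice connected components — 3D connectivity would fail wherever
   bone touches dark background axially at the knee/ankle ends of the crop.
3. **Bright-class resolution.** Bright components adjacent to background
   form the subcutaneous fat shell; bright islands enclosed by muscle are
   intramuscular fat and stay labelled muscle for volumetry — they are
   detected by `TA_Musc`, not excluded from the muscle volume.
4. **Cleanup.** Optional per-class in-plane binary closing
   (`closing_radius_voxels`, default 0 — at SNRs of 57–180
   threshold noise is negligible and closing erodes the thin fibula) and
   small-object removal (`min_component_voxels`, default 27): components
   below the size threshold merge into the majority class of their
   6-neighbours.
5. **Bone identification.** The larger bone component is the tibia, the
   second the fibula; ties break by greater mean cross-sectional area
   (component size divided by slices spanned). Stray fragments join the
   nearer major bone.

Slice extents are 1-based inclusive `(first, last)` pairs along the third
array axis. Phantoms lack anatomical landmarks, so extents are explicit
configuration rather than landmark detection.

Arteries come from subtraction angiography: the diastolic volume is
subtracted from the systolic one and the difference is thresholded at
`threshold_sd_mult` (default 5) times a robust noise estimate (median
absolute deviation), followed by small-object removal.

## The intramuscular-fat statistic

`TA_Musc = 100 · Pixel_High / Pixel_Musc`, where a muscle voxel is *high*
if its intensity strictly exceeds `threshold_multiplier` (default 1.5)
times the reference intensity of its neighbourhood. Design choices where
the convention is not fixed by the definition:

* **Neighbourhood**: an in-plane (2D, per axial slice) square window of
  radius 5 voxels, centre excluded. The statistic is defined on "pixels",
  i.e. slice-wise; window radius and 2D behaviour are configurable.
* **Reference statistic**: the median (default), because speckles cluster —
  a mean reference is dragged upward by the speckles themselves; both are
  available.
* **Validity**: voxels with fewer than `min_neighbors` (default 10) muscle
  neighbours (mask edges, isolated voxels) are excluded from numerator and
  denominator rather than imputed.
* **Threshold reading**: "over 1.5 times higher" is implemented as
  `I > 1.5 × ref`. The alternative grammatical reading (`I > 2.5 × ref`)
  is rejected but would be a one-line configuration change; control-leg
  values near 1.5% are consistent with either.

Because the speckles partially shadow their own local reference when they
are dense, recovery of a planted speckle fraction is validated to ±30%
relative; in practice the median reference keeps the error within a few
percent at fractions up to 0.15.

## The synthetic phantom

`phantom_spec()` defines a leg as concentric elliptic cylinders — a
subcutaneous fat shell around a muscle core (in-plane aspect ratio 0.78)
with two embedded bone cylinders and an optional axial artery tube — the
simplest geometry whose tissue volumes are analytically controllable.
Regions are realised by taking *exactly* the required number of voxels in
an elliptical-distance ordering, so requested and realised volumes agree to
well under the 2% contract. Bone discs are placed radius-aware along the
anterior–posterior axis so that strongly shrunken (affected) legs keep the
bones separated and inside the core.

Intensities follow the study conditions: muscle fixed at 100 arbitrary
units; fat and bone means solved from Michelson contrasts
(`|S1−S2|/(S1+S2)`) of 0.52 (fat/muscle) and 0.75 (bone/muscle), giving
means of ≈317 and ≈14; additive Gaussian noise per class with
`sd = mean/SNR` at SNRs of 180 (fat) and 57 (muscle); bone and background
carry the muscle-level noise floor. At these SNRs a Gaussian approximation
to Rician noise is appropriate. Intramuscular fat is planted as spherical
clusters (radius 1–2 voxels) at uniformly random interior muscle locations,
taking fat-class intensity; placements whose dilated cluster would touch
the subcutaneous shell or background are rejected, because intramuscular
fat is interior to the muscle and a boundary-touching cluster would merge
with the bright shell component. The cluster-size distribution is a
modelling choice — no quantitative description of speckle spatial structure
exists to emulate.

All randomness flows from one seed through named streams
(`speckle`, `noise`, `mra_systole`, …), so adding a tissue never perturbs
another tissue's draws, and identical specifications are bit-identical.

`cohort_spec()` adds the group structure: affected:unaffected multiplier
distributions per tissue (defaults: muscle 0.60 ± 0.078, tibia 0.92 ± 0.06,
fibula 0.89 ± 0.068, subcutaneous fat 1.05 ± 0.069 — the reported effect
sizes), control right:left distributions centred at 1 with the reported
control spreads, and a ×5 intramuscular-fat enrichment for affected legs
(control TA ≈ 1.5%, affected ≈ 7%). Bilateral participants draw
affected-style multipliers independently for both legs. Every drawn
multiplier is recorded for parameter-recovery testing.

**What the phantom does not emulate:** partial-volume boundary voxels,
bias fields, motion, chemical-shift artefacts, anatomical shape variation,
bone marrow (bones are uniformly dark), and individual muscle groups.
Segmentation accuracy on phantoms (Dice ≈ 1) therefore bounds algorithmic
error only; on real images the semi-automated protocol's inter-operator
variation (the FEM experiment) is the relevant uncertainty.

## Statistics

* Summaries are mean ± sample SD (n−1 denominator — the convention is
  verifiable against the published SDs, e.g. the leg-ratio set) with
  quartiles by linear interpolation.
* The two-sample Kolmogorov–Smirnov test evaluates both empirical CDFs at
  every distinct pooled value, so D is well defined under ties. The exact
  two-sided p-value is computed by dynamic-programming lattice-path
  counting over all `choose(n+m, n)` label assignments, with tie groups
  weighted by binomial coefficients (equivalent to averaging over all
  tie-breaking orders); integer arithmetic makes it exact up to
  `n + m ≤ 30` (the default `exact_limit`). Beyond that a seeded
  permutation test (10⁵ resamples) approximates the same null, and an
  asymptotic Kolmogorov-series method with effective size `nm/(n+m)` is
  available. The engine is validated against brute-force enumeration for
  all `n + m ≤ 12` and against the reference implementation on untied
  data.
* FEM (fractional error of the mean), the reproducibility metric, is the
  cross-operator coefficient of variation `100·SD/mean`; the SEM-based
  alternative was considered and rejected as the default because the
  published values are consistent with the CV reading.

One convention could not be resolved: the source analysis reports
P = 0.0069 for its fully separated 5-vs-4 contrasts, whereas the standard
exact convention gives 2/C(9,4) ≈ 0.0159 (its 10-vs-6 value 0.00026 *does*
match 2/C(16,6)). D values are therefore the validated quantity for that
contrast family; p-value conventions are documented, not guessed.

## Problem sizes and numerical choices

The shipped tests and validation experiments run phantoms at reduced
resolution — typically 64×64×48 voxels at 2×2×3 mm and 32×32×24 at
4×4×5 mm for replicated cohort experiments, with control-proportioned
target volumes (muscle 220, fat 150, tibia 48, fibula 9 cm³) — sizes chosen
so the full suite exercises every stage, including 20-replicate null
cohorts and 5-replicate parameter recovery, in well under a minute per
experiment. The default `phantom_spec()` is a full-scale control leg
(1 mm isotropic voxels, 270 mm leg, muscle 1150 cm³). Degenerate inputs
fail loudly: constant images (no intensity modes), empty muscle masks,
all-background label maps, inverted slice extents, zero ratio denominators
at the single-measurement level (the cohort table records `NA` instead
when a leg legitimately measures zero, e.g. TA on a speckle-free phantom).

Printed-table rounding in rendered outputs is half-away-from-zero: volumes
and percentages to 1 decimal, ratios to 2; internal computation is always
full precision.

## Known limitations

* The segmentation emulation is validated against phantom truth, not
  against the original manual segmentations, which are not public.
* Absolute `TA_Musc` values depend on the (unpublished) neighbourhood
  convention of the original analysis; the shipped fixture table is the
  reference for those, while the implementation's convention is fully
  specified and configurable.
* Two printed cells in the source tables are internally inconsistent with
  their own printed inputs (one TA ratio, and two group SDs that derive
  from rounded rather than full-precision per-leg values); the test suite
  documents each and asserts the recomputed value.
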
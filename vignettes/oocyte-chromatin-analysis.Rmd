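---
title: "Chromocenter morphometry, mobility and RNA-based biological age in mouse oocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromocenter morphometry, mobility and RNA-based biological age in mouse oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oochromatin)
```

## The biology and the measurements

In fully grown germinal-vesicle (GV) mouse oocytes, pericentric
heterochromatin — megabases of major-satellite repeats flanking each
centromere — coalesces into a small number of compact nuclear bodies
called chromocenters. Their organization tracks a key developmental
switch: transcriptionally active oocytes keep chromocenters dispersed
through the nucleoplasm (the NSN, non-surrounded-nucleolus
configuration), while transcriptionally silent oocytes dock most of them
onto the nucleolar surface (SN, surrounded nucleolus). Genotoxic stress
(acute gamma-irradiation) and reproductive aging both remodel this
architecture: chromocenters become markedly more mobile in SN oocytes,
and in NSN oocytes the satellite fibers unfold into distended structures
reminiscent of senescence-associated distension of satellite DNA (SADs).
Senescent oocytes additionally shed extrachromosomal (ec) satellite
fragments, a chromosome-instability marker.

`oochromatin` implements the quantitative side of this kind of study as
reusable, testable components:

* **morphometry** — 3D segmentation of chromocenters from fluorescence
  stacks and per-region volume, surface area, sphericity, nucleolar
  contact (NSN/SN call), satellite line scans, and ec-fragment calls;
* **tracking** — linking of time-lapse chromocenter detections and the
  mobility statistics (per-track total path length and mean speed) with
  group comparisons;
* **clock** — an oocyte RNA age predictor (gradient-boosted regression
  trees) with cross-validation, plus attribution of a profile's
  deviation from a young-control baseline to genes and ontology-level
  processes;
* **stats** — the named statistical procedures (Mann-Whitney, unpaired
  t-test with a D'Agostino-Pearson normality pre-check, Cohen's d,
  one-way ANOVA with Tukey HSD, five-number box-plot summaries);
* **synthetic data** — phantom nuclei, motion regimes and transcriptome
  cohorts with known ground truth, so that every analysis stage can be
  verified by parameter recovery without microscope or sequencing data.

Because the original microscopy and live-imaging data are measurements
on real oocytes, the package treats the published summary statistics as
*generator calibrations*: the presets plant objects whose counts,
volumes, speeds and path lengths match those summaries, and the analysis
pipeline is required to recover them. This is a statement about the
pipeline's correctness, not a re-measurement of oocytes.

## Segmentation model and parameters

Segmentation follows the surface-segmentation recipe used on SR-SIM
stacks of GV nuclei: Gaussian smoothing at a 0.05 µm grain, an absolute
DAPI intensity threshold of 8700 (the instrument scale of the original
detector), 26-connected 3D components, and removal of components smaller
than 2.30 µm³. All three values are exposed in `segmentation_params()`
with those defaults. Two deliberate generalizations:

* a **relative threshold mode** (fraction of the 99.9th intensity
  percentile, default 0.6) for stacks on other detector scales, since an
  absolute count of 8700 is meaningless off-instrument;
* the boundary case `volume == min_volume` **passes** the filter.

Volumes are voxel counts times the anisotropic voxel volume. Surface
area is the area of the 0.5-level isosurface of the (lightly smoothed)
binary mask, extracted by marching tetrahedra with the physical voxel
spacing; sphericity is `pi^(1/3) * (6V)^(2/3) / A`, which the source
figures report without defining — this is the standard Wadell form,
equal to 1 for a sphere. On digitized test shapes at 0.05 µm sampling
the estimator reproduces the closed-form spheroid value within 0.005;
at the coarse phantom scale (0.15 x 0.15 x 0.30 µm voxels) sphericity
can overshoot 1 by a few percent on small regions, which is why the
region invariant allows a 5% mesh tolerance.

The NSN/SN call is an operationalization of a qualitative description
("most chromocenters become associated with the nucleolus"): a nucleus
is SN when more than half its chromocenters lie within 0.2 µm of the
nucleolar surface. Both the contact distance and the majority threshold
are config knobs.

ec-fragment detection re-segments the satellite channel with no
biological minimum volume (only a two-voxel speckle floor), keeps
components below the chromocenter minimum (2.30 µm³) and calls a
fragment when the component centroid is more than 1.0 µm from every
segmented chromocenter voxel. Centroid-to-surface distance was chosen
over surface-to-surface because it is robust to ragged fragment shapes.

## The nucleus phantom generator

Each phantom nucleus is a sphere of nucleoplasm (default background
3000 on the 16-bit instrument-like scale) with a central DAPI-poor
nucleolus and a planted set of chromocenters. A chromocenter is not a
hard ball: it is a bundle of 5–20 anisotropic Gaussian "fiber" kernels
inside a bounding ellipsoid, so that line scans across it have real
structure to resolve. Planted counts are drawn from a rounded normal
clipped to [1, 40]; planted volumes from a lognormal **left-truncated at
2.533 µm³** whose truncated mean/SD are moment-matched to the target
summary statistics. The truncation is essential: published volume
summaries were measured after the 2.30 µm³ filter, so they describe a
truncated distribution; matching an untruncated lognormal to the SN
moments (6.04 ± 5.6 µm³) would put roughly a fifth of its mass below
the filter and make count recovery impossible by construction. The
floor sits 10% above the filter so borderline objects are not lost to
segmentation jitter.

The renderer's central calibration: for each object, the intensity
scale is chosen so that the **8700-level set of the PSF-blurred field
encloses exactly the planted volume**. Segmentation at default
parameters therefore recovers planted counts and volumes up to noise,
and any residual bias is a pipeline defect, not a generator artifact.
Poisson noise (quanta of 25) and Gaussian read noise (SD 120) are
applied after the PSF, and stored intensities saturate at the 16-bit
ceiling exactly as on a real detector — bright chromocenter cores may
clip, which leaves the threshold-level geometry untouched because the
PSF acts before quantization.

Distension (`distension_factor` d > 1) models satellite unfolding: fiber
positions and the envelope scale by d, the transverse bundle width by
sqrt(d) (a loosening bundle widens while its spacing grows faster), and
each kernel's voxelized field is normalized to a fixed total intensity,
so the object integral is conserved to floating-point precision. Consequences that the tests exercise: total object
intensity is unchanged, fiber-to-fiber line-scan spacing grows, the
thresholded volume grows and sphericity falls (matching the reported
post-irradiation trend), and at large d an object can fragment at the
threshold — which is also seen in real distended chromocenters. Because
the planted-volume level calibration is defined at d = 1, distended
phantoms have known *intensity* ground truth but only qualitative volume
ground truth. Placement uses the condensed object's exclusion radius regardless of
distension, so matched seeds plant identical structures and unfolded
peripheries may interdigitate, as they do in crowded irradiated
nuclei. On rare crowded draws the
placement margins are progressively relaxed instead of failing the
nucleus; genuinely impossible configurations still raise a generation
error naming the config.

Phantom presets render a 9 µm-radius nucleus at 0.15 x 0.15 x 0.30 µm
voxels — about 1.2 million voxels per nucleus. This is the package's
chosen problem size for cohort experiments: fine enough that the
smallest plantable chromocenter spans several hundred voxels, small
enough that a 50-phantom cohort renders and segments in about a minute
per preset on one CPU. The config default voxel size (0.04, 0.04,
0.091) µm mirrors SR-SIM sampling and is used in the fine-scale
line-scan and measurement tests. What the phantoms deliberately do not
emulate: structured-illumination reconstruction artifacts, chromatin
other than chromocenters (no euchromatin texture), nucleolar
substructure, and optical aberrations. Passing recovery tests therefore
shows the pipeline is correct on well-calibrated globular objects, not
that it is robust to every real-microscope pathology.

## Motion regimes and calibration

Tracks are sampled every 5 minutes for 5 hours (61 frames), the
live-imaging schedule. Step lengths are Rayleigh-distributed — the
published data constrain only means, and Rayleigh is the natural
isotropic-displacement magnitude — scaled so that the expected mean
speed (total path over duration) equals the target. Regimes differ only
in direction structure, so the calibration holds for all of them:
control chromocenters perform anchored oscillations confined to a 2 µm
shell (directions are resampled when a step would leave the shell,
preserving step length), while irradiated and senescent chromocenters
mix a persistent per-track drift with isotropic steps
(`directed_fraction` 0.6), modelling linear displacement after
nucleolar detachment.

The printed control speed/path pair is internally inconsistent at face
value (0.003 µm/s x 18000 s = 54 µm, but the printed mean path is
56.5 µm, presumably a rounding of speed to one significant digit).
Presets are therefore calibrated to the **printed path lengths**
(56.5 / 89.9 / 90.9 µm, i.e. speeds 0.00314 / 0.00499 / 0.00505 µm/s),
which reproduces both printed numbers within 5%. One known bias: with a
small confinement radius and a high target speed, shell-capping of rare
long steps shortens the measured path by up to ~2%; at the control
preset's speed the effect is below 0.5%.

Per-track speed is defined as total path over elapsed time — the
definition consistent with the published paired speed/path values — so
`speed x duration = path` holds to machine precision on every track, and
group comparisons use one-way ANOVA with Tukey HSD exactly as in the
source analyses. Linking is greedy globally-nearest-pair with a 3 µm
per-interval gate (about ten times the irradiated mean step), no gap
closing, and no split/merge logic: a chromocenter split appears as a new
track, which is the documented behavior.

## The RNA age clock

The clock is a gradient-boosted regression-tree model (300 trees, depth
3, learning rate 0.05, subsample 0.8 — unpublished in the source, chosen
for stability at n ≈ 200 training profiles) on log2(CPM + 1) expression.
The normalization itself was unspecified upstream ("normalized count
value"); log2-CPM was chosen as the least surprising bulk-RNA choice and
is recorded in the model object so that the baseline difference D is
reproducible. Samples flagged as irradiated are trained against a
*senescence-equivalent age* — by default the 90th percentile of training
ages — which makes explicit and tunable the otherwise unstated mechanism
by which a clock can "predict advanced biological age for irradiated
transcriptomes" while staying accurate on controls. Cross-validation is
5-fold, stratified by target-age quantile, scored by mean absolute error
in days.

Attribution follows the published two-step recipe exactly: per gene,
`impact = I * |D|` where I is the model's normalized split-gain
importance and D the difference of the profile's normalized value from a
young-control baseline profile; per process, impacts are summed over the
genes annotated to it and min–max normalized to [0, 1] **within one
contrast** (one heatmap column) — the per-condition reading of the
published heatmap; an all-zero column maps to zeros, and a degenerate
constant non-zero column to ones. The toy ontology has 29 top-level
processes, each gene annotated to exactly one.

The synthetic cohort plants a monotone log-linear age program in 10% of
1000 genes over ages 20–430 days (slope 0.005 log2-units/day, i.e. about
a 2-fold change across the range), negative-binomial counts with
dispersion 0.1, and an irradiation-like shift that moves responsive
genes of perturbed samples 300 days-equivalent along the program;
perturbation is assigned to young samples, mirroring designs that
irradiate young oocytes. The published clock's headline numbers (78.8 d
cross-validated MAE on 199 ArchS4 profiles, 7.29 d training MAE,
>350-day predictions for young irradiated oocytes) require those
external datasets and are **not** reproduced; the clock is instead held
to property-based standards on synthetic cohorts: cross-validated MAE
below a quarter of the age range, label-permutation control no better
than predicting the mean age, perturbed samples predicted older than
age-matched controls in at least 95% of cases, and processes holding
planted age genes outranking empty processes in at least 9 of 10 seeds
(the seed sweep runs on reduced cohorts — 400 genes, 120 samples, 150
trees — to keep the suite fast; the effect is large and insensitive to
this size).

## Statistics layer

`compare_two()` mirrors the source's test-selection rule: two-sided
unpaired t-test unless the D'Agostino–Pearson omnibus test rejects
normality (p < 0.05) in either group, in which case Mann–Whitney is
used. The omnibus test is implemented from the standard Z(skewness) and
Z(kurtosis) transforms (no installed R package provides it) and is
verified in the tests against frozen reference values from an
independent implementation; note that for *exactly* symmetric samples
the reference's skew term applies a y = 0 → 1 workaround while this
implementation returns the mathematically clean Z1 = 0. Cohen's d uses
the pooled-SD form. Quartiles and box-plot five-number summaries use
linear interpolation between order statistics (R quantile type 7),
matching common plotting defaults. Confidence intervals come from the
underlying `t.test`/`wilcox.test`/`TukeyHSD` machinery; the original
software's (GraphPad) interval conventions are not reproduced
bit-for-bit, so the suite validates calibration by simulation instead
(type-I error within ±1 point of the 5% nominal level over 10,000 null
replicates).

On the published count summaries (7.9 ± 1.4 vs 11.7 ± 1.7), groups
reconstructed with exactly those sample moments give Cohen's d of 2.37
or 2.51 depending on which group carries n = 7 — the legend's
n-assignment is ambiguous — bracketing the published 2.23 within the
acceptance band [2.0, 2.6].

## Worked example

```{r example, eval = FALSE}
library(oochromatin)

# render one SN-configuration phantom and segment it
ph <- gen_nucleus_phantom(preset("sn_default", seed = 1))
regions <- segment_chromocenters(ph$stack)
length(regions)                       # chromocenter count
mean(sapply(regions, `[[`, "volume")) # mean volume, um^3
classify_configuration(regions, ph$ground_truth$nucleolus,
                       stack = ph$stack)

# simulate and compare the three mobility groups
metrics <- do.call(rbind, lapply(
  c("ctrl_motion", "irrad_motion", "senesc_motion"),
  function(p) trackset_metrics(gen_trackset(preset(p, seed = 1))$tracks)))
cohort_mobility(metrics)$summary

# fit the RNA clock on a synthetic cohort and attribute process impacts
coh <- gen_transcriptome_cohort(preset("clock_default", seed = 1))
X <- normalize_counts(coh$counts)
model <- fit_age_clock(X, coh$ages, coh$perturbed, seed = 1)
cv <- cross_validate_clock(X, coh$ages, coh$perturbed, k = 5, seed = 1)
cv$mae
```

## Numerical choices and degenerate inputs

* Coordinates: arrays are indexed (y, x, z); the centre of voxel
  (i, j, k) sits at ((i − 0.5) vy, (j − 0.5) vx, (k − 0.5) vz) µm.
  Voxel size is a *named* vector `c(x=, y=, z=)` and is required — there
  is no silent default when reading a stack.
* Peak detection in line scans uses topographic prominence with ties
  broken toward the lower coordinate; the default prominence is 10% of
  the profile's dynamic range.
* Linking ties (equal distances) are broken toward the lower track id.
* Single-detection tracks report zero metrics with a degenerate flag;
  stationary tracks have undefined straightness (NA).
* Groups with one nucleus/track are summarized with an explicit
  `sd_undefined` flag; groups with fewer than two tracks are excluded
  from hypothesis tests with a warning.
* `xgboost` is run single-threaded with an explicit seed, making fits
  and cross-validation deterministic and invariant to sample order.
* Generation is a pure function of the config, including its seed; no
  hidden global state survives a generator call.

## Known limitations

Phantoms are geometric, not physical: no SIM reconstruction artifacts,
no chromatin polymer mechanics, no nucleolar biophysics. The tracking
module has no gap closing or split/merge handling, no MSD/diffusion
fitting, and no nucleolar-detachment event detection. The clock module
does not reproduce the external-data MAEs, performs no differential
expression or enrichment analysis, and its toy one-process-per-gene
ontology only optionally emulates multi-membership (genes absent from
the annotation are ignored with a logged count). Maximum-intensity
-projection-based volumes, offered for comparability with
projection-based quantification, are projected-area-derived quantities
and are never mixed with full-3D volumes.
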
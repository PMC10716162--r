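# oochromatin

Quantitative analysis of pericentric heterochromatin (chromocenter)
organization in mouse germinal-vesicle (GV) oocytes, and of how acute
irradiation and reproductive aging remodel it. The package is aimed at
groups doing nuclear-architecture imaging and oocyte transcriptomics who
need the measurement side of such studies as tested, reusable code.

In GV oocytes, major-satellite repeats coalesce into a handful of
compact chromocenters whose number, volume and nucleolar association
track the oocyte's developmental state (dispersed **NSN** vs
nucleolus-associated **SN** configuration). Irradiation and senescence
increase chromocenter mobility, unfold satellite fibers into distended
structures, and — in senescent oocytes — produce extrachromosomal (ec)
satellite fragments. `oochromatin` implements:

* **3D chromocenter morphometry** — Gaussian smoothing at a 0.05 µm
  grain, absolute intensity threshold 8700 (with a relative mode for
  other detectors), 26-connected components, 2.30 µm³ minimum volume;
  per-region volume `V`, isosurface area `A` (marching tetrahedra) and
  sphericity `psi = pi^(1/3) (6V)^(2/3) / A`; NSN/SN classification by
  nucleolar contact; satellite line scans with peak-spacing (fiber
  distance) estimates; ec-fragment calls and cohort prevalence.
* **Chromocenter tracking** — greedy globally-nearest-pair linking of
  per-frame detections, per-track total path length `L` and mean speed
  `v = L / T` over the 5-min x 5-h imaging schedule, group summaries
  with one-way ANOVA + Tukey HSD.
* **An oocyte RNA age clock** — gradient-boosted regression trees on
  log2(CPM+1) expression predicting age in days, 5-fold cross-validated
  MAE, and impact attribution `impact_g = I_g * |D_g|` (model importance
  times absolute deviation from a young-control baseline), summed per
  ontology process and min-max normalized to [0, 1] per contrast.
* **Synthetic data generators** — nucleus phantoms (fiber-bundle
  chromocenters with exact planted volumes, optional distension and
  planted ec fragments), three motion regimes, and age-structured
  transcriptome cohorts, each a pure function of a seeded config with
  serialized ground truth. Presets encode the published summary
  statistics (NSN 7.9 ± 1.4 vs SN 11.7 ± 1.7 chromocenters; volumes
  11.8 ± 7.2 vs 6.04 ± 5.6 µm³; mean paths 56.5 / 89.9 / 90.9 µm for
  control / irradiated / senescent over 5 h).

## Worked example

```r
library(oochromatin)

# one SN-configuration phantom nucleus, segmented with default params
ph   <- gen_nucleus_phantom(preset("sn_default", seed = 1))
regs <- segment_chromocenters(ph$stack)
length(regs)
#> [1] 11
round(mean(sapply(regs, `[[`, "volume")), 2)
#> [1] 6.32
classify_configuration(regs, ph$ground_truth$nucleolus, stack = ph$stack)
#> [1] "SN"

# mobility of the three motion presets
metrics <- do.call(rbind, lapply(
  c("ctrl_motion", "irrad_motion", "senesc_motion"),
  function(p) trackset_metrics(gen_trackset(preset(p, seed = 1))$tracks)))
cohort_mobility(metrics)$summary
#>                  group n_tracks mean_speed_um_per_s sd_speed_um_per_s mean_path_um sd_path_um
#> 1 anchored_oscillatory       60         0.003125096      0.0002200420     56.25174   3.960757
#> 2    detached_directed       71         0.004987921      0.0003586987     89.78258   6.456576
#> 3   senescent_directed       55         0.005026062      0.0003666032     90.46911   6.598858
```

The phantom plants 11 chromocenters averaging ~6 µm³ docked on the
nucleolar surface; the pipeline segments all of them, recovers their
volumes, and calls the configuration SN. The simulated control group
moves at ~0.0031 µm/s (56 µm of path over 5 h) while the irradiated and
senescent groups travel ~90 µm at ~0.005 µm/s; Tukey HSD on these
metrics flags control vs irradiated as significant and irradiated vs
senescent as not, the published significance pattern.

```r
# RNA clock on a synthetic age cohort (200 samples, ages 20-430 days)
coh <- gen_transcriptome_cohort(preset("clock_default", seed = 1))
X   <- normalize_counts(coh$counts)
cv  <- cross_validate_clock(X, coh$ages, coh$perturbed, k = 5, seed = 2)
round(cv$mae, 1)
#> [1] 20.9
```

A cross-validated MAE of ~21 days on a 410-day age range shows the
clock recovers the planted aging program; irradiation-shifted samples
are predicted substantially older than age-matched controls.

## Command line

A thin wrapper over the same functions (see `inst/cli/oochromatin`):

```sh
oochromatin simulate nucleus --preset nsn_default --seed 1 --out out/
oochromatin segment --in out/nucleus.tif --channel dapi --out seg/
oochromatin simulate tracks --preset ctrl_motion --seed 1 --out trk/
oochromatin track --in trk/tracks.csv --by group --out mob/
oochromatin clock cv --counts c.tsv --meta m.tsv --k 5 --seed 7 --out cv/
```

Every run writes its outputs next to a `resolved_config.json` and a log,
so any artifact is reproducible from its config copy and seed.

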
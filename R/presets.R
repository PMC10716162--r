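#' Preset registry calibrated to published oocyte summary statistics
#'
#' Each preset returns a generator configuration whose parameters encode a
#' published summary statistic for mouse germinal-vesicle oocytes:
#' \describe{
#'   \item{nsn_default}{NSN nucleus phantom; chromocenter count 7.9 ± 1.4,
#'     chromocenter volume 11.8 ± 7.2 µm³ (post-volume-filter moments).}
#'   \item{sn_default}{SN nucleus phantom; count 11.7 ± 1.7, volume
#'     6.04 ± 5.6 µm³, chromocenters on the nucleolar surface.}
#'   \item{nsn_irradiated}{NSN phantom 24 h after acute irradiation:
#'     distension factor 1.6 (published volumes roughly quadruple, i.e.
#'     a ~1.6x linear unfolding of satellite fibers).}
#'   \item{nsn_senescent}{NSN phantom from a senescent ovary: distension
#'     1.5 plus planted extrachromosomal satellite fragments.}
#'   \item{ctrl_motion}{anchored oscillatory motion at the nucleolus; mean
#'     total path 56.5 µm over 5 h (mean speed 56.5/18000 ≈ 0.0031 µm/s,
#'     printed as 0.003), 60 tracks.}
#'   \item{irrad_motion}{directed motion after nucleolar detachment; mean
#'     path 89.9 µm (speed ≈ 0.005 µm/s), 71 tracks.}
#'   \item{senesc_motion}{directed motion in senescent oocytes; mean path
#'     90.9 µm (speed ≈ 0.005 µm/s), 55 tracks.}
#'   \item{clock_default}{age-structured transcriptome cohort: 200 samples,
#'     1000 genes, ages 20-430 days, 10% age-responsive genes, 29 ontology
#'     processes, irradiation-like shift of 300 days-equivalent.}
#' }
#'
#' Phantom presets render at 0.15 x 0.15 x 0.30 µm voxels in a 9 µm
#' nucleus: coarse enough to keep a 50-phantom cohort tractable on one
#' CPU, fine enough that the smallest plantable chromocenter (2.53 µm³)
#' spans hundreds of voxels.
#'
#' @param name preset name (see above).
#' @param seed RNG seed stored in the returned config.
#' @return a `nucleus_phantom_config`, `motion_config` or
#'   `transcriptome_config`.
#' @export
preset <- function(name, seed = 1) {
  registry <- c("nsn_default", "sn_default", "nsn_irradiated",
                "nsn_senescent", "ctrl_motion", "irrad_motion",
                "senesc_motion", "clock_default")
  if (!name %in% registry)
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(registry, collapse = ", ")))
  phantom_base <- function(...) {
    args <- utils::modifyList(
      list(nucleus_radius = 9, nucleolus_radius = 3,
           voxel_size = c(x = 0.15, y = 0.15, z = 0.30),
           psf_sigma = 0.12, poisson_scale = 25, gaussian_sd = 120,
           seed = seed),
      list(...))
    do.call(nucleus_phantom_config, args)
  }
  switch(name,
    nsn_default = phantom_base(
      configuration = "NSN",
      n_chromocenters_mean = 7.9, n_chromocenters_sd = 1.4,
      volume_mean = 11.8, volume_sd = 7.2),
    sn_default = phantom_base(
      configuration = "SN", nucleolus_radius = 3.2,
      n_chromocenters_mean = 11.7, n_chromocenters_sd = 1.7,
      volume_mean = 6.04, volume_sd = 5.6),
    nsn_irradiated = phantom_base(
      configuration = "NSN",
      n_chromocenters_mean = 7.9, n_chromocenters_sd = 1.4,
      volume_mean = 11.8, volume_sd = 7.2,
      distension_factor = 1.6),
    nsn_senescent = phantom_base(
      configuration = "NSN",
      n_chromocenters_mean = 7.9, n_chromocenters_sd = 1.4,
      volume_mean = 11.8, volume_sd = 7.2,
      distension_factor = 1.5, n_fragments = 2),
    ctrl_motion = motion_config(
      regime = "anchored_oscillatory",
      target_mean_speed = 56.5 / 18000,
      confinement_radius = 2, n_tracks = 60, seed = seed),
    irrad_motion = motion_config(
      regime = "detached_directed",
      target_mean_speed = 89.9 / 18000,
      directed_fraction = 0.6, n_tracks = 71, seed = seed),
    senesc_motion = motion_config(
      regime = "senescent_directed",
      target_mean_speed = 90.9 / 18000,
      directed_fraction = 0.6, n_tracks = 55, seed = seed),
    clock_default = transcriptome_config(seed = seed)
  )
}
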
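#' Configuration for a synthetic nucleus phantom
#'
#' Describes one germinal-vesicle nucleus phantom: a spherical nucleoplasm
#' containing a central nucleolus and a set of globular chromocenters, each
#' rendered as a bundle of overlapping Gaussian "fiber" kernels inside a
#' bounding ellipsoid (so that line scans across a chromocenter resolve
#' fiber-to-fiber structure). Chromocenter counts are drawn from a rounded
#' normal clipped to \[1, 40\]; volumes from a lognormal left-truncated at
#' `min_plant_volume` whose truncated mean/SD are moment-matched to
#' `volume_mean`/`volume_sd`.
#'
#' Intensities are on a 16-bit instrument-like scale: the rendered
#' 8700-intensity level set of each chromocenter (before blur and noise)
#' encloses exactly its planted volume, so default-parameter segmentation
#' recovers planted counts and volumes.
#'
#' @param nucleus_radius,nucleolus_radius µm; nucleolus must fit inside.
#' @param configuration `"NSN"` (chromocenters dispersed through the
#'   nucleoplasm, periphery included) or `"SN"` (centres on the nucleolar
#'   surface).
#' @param n_chromocenters_mean,n_chromocenters_sd count distribution
#'   (normal, rounded, clipped to \[1, 40\]); `sd = 0` plants exactly
#'   `round(mean)`.
#' @param volume_mean,volume_sd target arithmetic mean/SD of planted
#'   chromocenter volume, µm³.
#' @param min_plant_volume truncation floor for planted volumes, µm³.
#' @param distension_factor linear factor >= 1; scales fiber positions and
#'   the envelope while conserving each kernel's integrated intensity
#'   (satellite distension: spacing grows, total signal is conserved).
#' @param voxel_size named `c(x=, y=, z=)` µm.
#' @param psf_sigma isotropic Gaussian PSF sigma, µm.
#' @param poisson_scale,gaussian_sd noise: intensities are Poisson-resampled
#'   in quanta of `poisson_scale` (0 = off) then perturbed with additive
#'   Gaussian read noise of SD `gaussian_sd` (0 = off).
#' @param n_fragments number of extrachromosomal satellite fragments to
#'   plant (satellite channel), each placed > 2 µm from every chromocenter.
#' @param fragment_volume_range µm³ range for planted fragment volumes.
#' @param background nucleoplasm background intensity (DAPI channel).
#' @param n_fibers_range number of Gaussian fiber kernels per chromocenter.
#' @param fiber_sigma fiber cross-section sigma, µm.
#' @param seed integer RNG seed; the generator is a pure function of the
#'   config including the seed.
#' @return object of class `nucleus_phantom_config`.
#' @export
nucleus_phantom_config <- function(nucleus_radius = 4,
                                   nucleolus_radius = 1.5,
                                   configuration = c("NSN", "SN"),
                                   n_chromocenters_mean = 7.9,
                                   n_chromocenters_sd = 1.4,
                                   volume_mean = 11.8,
                                   volume_sd = 7.2,
                                   min_plant_volume = 2.533,
                                   distension_factor = 1,
                                   voxel_size = c(x = 0.04, y = 0.04, z = 0.091),
                                   psf_sigma = 0.1,
                                   poisson_scale = 25,
                                   gaussian_sd = 120,
                                   n_fragments = 0,
                                   fragment_volume_range = c(0.3, 0.9),
                                   background = 3000,
                                   n_fibers_range = c(5, 20),
                                   fiber_sigma = 0.12,
                                   seed = 1) {
  configuration <- match.arg(configuration)
  voxel_size <- normalize_voxel_size(voxel_size)
  stopifnot(nucleus_radius > 0, nucleolus_radius > 0)
  if (nucleolus_radius >= nucleus_radius)
    stop("nucleolus_radius must be < nucleus_radius")
  if (distension_factor < 1) stop("distension_factor must be >= 1")
  if (n_chromocenters_mean < 1) stop("n_chromocenters_mean must be >= 1")
  if (n_chromocenters_sd < 0) stop("n_chromocenters_sd must be >= 0")
  if (volume_mean <= min_plant_volume)
    stop("volume_mean must exceed min_plant_volume")
  if (volume_sd < 0) stop("volume_sd must be >= 0")
  if (n_fragments < 0) stop("n_fragments must be >= 0")
  if (psf_sigma < 0 || poisson_scale < 0 || gaussian_sd < 0)
    stop("psf_sigma, poisson_scale and gaussian_sd must be >= 0")
  ln <- lognormal_params_for_mean_sd(volume_mean, volume_sd,
                                     lower = min_plant_volume)
  structure(list(
    nucleus_radius = nucleus_radius,
    nucleolus_radius = nucleolus_radius,
    configuration = configuration,
    n_chromocenters_mean = n_chromocenters_mean,
    n_chromocenters_sd = n_chromocenters_sd,
    volume_mean = volume_mean,
    volume_sd = volume_sd,
    min_plant_volume = min_plant_volume,
    volume_lognormal_mu = ln["mu"],
    volume_lognormal_sigma = ln["sigma"],
    distension_factor = distension_factor,
    voxel_size = voxel_size,
    psf_sigma = psf_sigma,
    poisson_scale = poisson_scale,
    gaussian_sd = gaussian_sd,
    n_fragments = n_fragments,
    fragment_volume_range = fragment_volume_range,
    background = background,
    threshold_ref = 8700,
    n_fibers_range = n_fibers_range,
    fiber_sigma = fiber_sigma,
    seed = as.integer(seed)
  ), class = "nucleus_phantom_config")
}

#' Lognormal parameters matching a target mean/SD, optionally left-truncated
#'
#' For `lower = 0` this is closed-form moment matching. For `lower > 0` the
#' (mu, sigma) of the parent lognormal are found numerically so that the
#' TRUNCATED distribution (X | X > lower) has the requested arithmetic
#' mean and SD; summary statistics published after a volume filter describe
#' a truncated distribution, and presets must match them post-filter.
#'
#' @param mean,sd target arithmetic moments of the (truncated) variable.
#' @param lower truncation floor (0 = no truncation).
#' @return named vector `c(mu=, sigma=)` of the parent lognormal.
#' @export
lognormal_params_for_mean_sd <- function(mean, sd, lower = 0) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(mu = log(mean), sigma = 0))
  sigma2 <- log(1 + (sd / mean)^2)
  start <- c(log(mean) - sigma2 / 2, sqrt(sigma2))
  if (lower <= 0) return(c(mu = start[1], sigma = start[2]))

  trunc_moments <- function(mu, sigma) {
    la <- log(lower)
    z0 <- (mu - la) / sigma
    p0 <- pnorm(z0)
    m1 <- exp(mu + sigma^2 / 2) * pnorm(z0 + sigma) / p0
    m2 <- exp(2 * mu + 2 * sigma^2) * pnorm(z0 + 2 * sigma) / p0
    c(m1, sqrt(pmax(m2 - m1^2, 0)))
  }
  obj <- function(p) {
    mm <- trunc_moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(start[1], log(start[2])), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# draw n volumes from the truncated lognormal of a phantom config by
# inverse-CDF sampling (exact, constant cost even for extreme truncation)
draw_volumes <- function(config, n) {
  mu <- config$volume_lognormal_mu
  sigma <- config$volume_lognormal_sigma
  if (sigma == 0) return(rep(exp(mu), n))
  qlo <- stats::plnorm(config$min_plant_volume, mu, sigma)
  stats::qlnorm(runif(n, qlo, 1), mu, sigma)
}

draw_count <- function(config) {
  n <- if (config$n_chromocenters_sd == 0) round(config$n_chromocenters_mean)
       else round(rnorm(1, config$n_chromocenters_mean,
                        config$n_chromocenters_sd))
  min(max(n, 1L), 40L)
}
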
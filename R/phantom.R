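#' Generate a synthetic nucleus phantom with known ground truth
#'
#' Renders a germinal-vesicle nucleus as a two-channel 3D stack (`dapi`,
#' `satellite`) containing a spherical nucleoplasm, a DAPI-poor nucleolus,
#' and chromocenters built from bundles of Gaussian fiber kernels. Each
#' chromocenter's intensity is scaled so that its 8700-level set (the
#' default absolute segmentation threshold) encloses exactly the planted
#' volume before blur and noise; a Gaussian PSF and Poisson/Gaussian noise
#' are then applied. `NSN` phantoms disperse chromocenters through the
#' nucleoplasm (periphery included, clear of the nucleolus); `SN` phantoms
#' place them on the nucleolar surface. A `distension_factor > 1` scales
#' fiber positions and envelope by that linear factor while conserving each
#' kernel's integrated intensity.
#'
#' @param config a [nucleus_phantom_config()].
#' @return list with elements `stack` (an [image_stack()]) and
#'   `ground_truth` (planted chromocenters, fragments, nucleolus geometry).
#' @export
gen_nucleus_phantom <- function(config) {
  stopifnot(inherits(config, "nucleus_phantom_config"))
  set.seed(config$seed)
  vs <- config$voxel_size
  R <- config$nucleus_radius
  half <- R + 0.7
  dims <- c(max(3L, ceiling(2 * half / vs["y"])),
            max(3L, ceiling(2 * half / vs["x"])),
            max(3L, ceiling(2 * half / vs["z"])))
  names(dims) <- NULL
  center <- c(y = dims[1] / 2 * vs[["y"]],
              x = dims[2] / 2 * vs[["x"]],
              z = dims[3] / 2 * vs[["z"]])

  n_cc <- draw_count(config)
  vols <- sort(draw_volumes(config, n_cc), decreasing = TRUE)
  r_base <- (3 * vols / (4 * pi))^(1 / 3)
  # mild random anisotropy of the bounding envelope, volume-preserving
  anis <- t(vapply(seq_len(n_cc), function(i) {
    f <- exp(runif(3, -0.13, 0.13))
    f / prod(f)^(1 / 3)
  }, numeric(3)))
  d <- config$distension_factor
  # placement extent is that of the CONDENSED object: distension leaves
  # the planted structure (count, volumes, centres, fibers) identical at
  # matched seeds, and unfolded peripheries are allowed to interdigitate
  # as they do in crowded irradiated nuclei
  r_eff <- 1.05 * r_base * apply(anis, 1, max)

  placement <- place_chromocenters(config, n_cc, r_eff, R)
  centers <- placement$centers  # n x 3 (y, x, z) um relative to nucleus center

  # --- background -----------------------------------------------------
  d2 <- dist2_array(dims, vs, center)
  nucleus_mask <- d2 <= R^2
  nucleolus_d2 <- dist2_array(dims, vs, center)  # nucleolus centred too
  dapi <- array(200, dim = dims)
  dapi[nucleus_mask] <- config$background
  dapi[nucleolus_d2 <= config$nucleolus_radius^2] <- 0.75 * config$background
  satellite <- array(100, dim = dims)
  satellite[nucleus_mask] <- 500

  # --- chromocenters --------------------------------------------------
  gt_cc <- data.frame(id = integer(0), volume_um3 = numeric(0),
                      y_um = numeric(0), x_um = numeric(0), z_um = numeric(0),
                      integrated_intensity = numeric(0))
  for (i in seq_len(n_cc)) {
    kern <- make_fiber_kernels(config, r_base[i], anis[i, ])
    ctr <- center + centers[i, ]
    ob <- render_object(dims, vs, ctr, kern, d, vols[i],
                        config$threshold_ref - config$background,
                        config$psf_sigma)
    dapi <- add_subfield(dapi, ob)
    satellite <- add_subfield(satellite, ob)
    gt_cc <- rbind(gt_cc, data.frame(
      id = i, volume_um3 = vols[i],
      y_um = ctr[["y"]], x_um = ctr[["x"]], z_um = ctr[["z"]],
      integrated_intensity = ob$integral))
  }
  gt_cc$envelope_y_um <- 1.25 * r_base * anis[, 1] * d
  gt_cc$envelope_x_um <- 1.25 * r_base * anis[, 2] * d
  gt_cc$envelope_z_um <- 1.25 * r_base * anis[, 3] * d

  # --- extrachromosomal fragments (satellite channel) ------------------
  gt_fr <- data.frame(id = integer(0), volume_um3 = numeric(0),
                      y_um = numeric(0), x_um = numeric(0), z_um = numeric(0))
  if (config$n_fragments > 0) {
    fr <- place_fragments(config, centers, r_eff, R)
    for (i in seq_len(nrow(fr))) {
      vf <- runif(1, config$fragment_volume_range[1],
                  config$fragment_volume_range[2])
      sig <- (3 * vf / (4 * pi))^(1 / 3) / 1.2
      kern <- list(pos = matrix(0, 1, 3),
                   dir = matrix(c(1, 0, 0), 1, 3),
                   sigma_long = sig, sigma_perp = sig)
      ctr <- center + fr[i, ]
      ob <- render_object(dims, vs, ctr, kern, 1, vf,
                          config$threshold_ref - 500, config$psf_sigma)
      satellite <- add_subfield(satellite, ob)
      gt_fr <- rbind(gt_fr, data.frame(
        id = i, volume_um3 = vf,
        y_um = ctr[["y"]], x_um = ctr[["x"]], z_um = ctr[["z"]]))
    }
  }

  # --- PSF + noise ------------------------------------------------------
  sig_vox <- config$psf_sigma / vs[c("y", "x", "z")]
  if (config$psf_sigma > 0) {
    dapi <- blur3d_cpp(dapi, dims, sig_vox)
    satellite <- blur3d_cpp(satellite, dims, sig_vox)
  }
  dapi <- apply_noise(dapi, config)
  satellite <- apply_noise(satellite, config)

  stack <- image_stack(list(dapi = dapi, satellite = satellite), vs)
  gt <- list(
    configuration = config$configuration,
    n_chromocenters = n_cc,
    chromocenters = gt_cc,
    fragments = gt_fr,
    nucleus = list(center_um = as.list(center), radius_um = R),
    nucleolus = list(center_um = as.list(center),
                     radius_um = config$nucleolus_radius),
    distension_factor = d,
    seed = config$seed
  )
  list(stack = stack, ground_truth = gt)
}

# squared physical distance of every voxel centre to a (y, x, z) um point
dist2_array <- function(dims, vs, point) {
  y2 <- ((seq_len(dims[1]) - 0.5) * vs[["y"]] - point[["y"]])^2
  x2 <- ((seq_len(dims[2]) - 0.5) * vs[["x"]] - point[["x"]])^2
  z2 <- ((seq_len(dims[3]) - 0.5) * vs[["z"]] - point[["z"]])^2
  arr <- array(0, dim = dims)
  sl <- outer(y2, x2, "+")
  for (k in seq_len(dims[3])) arr[, , k] <- sl + z2[k]
  arr
}

random_unit <- function(n = 1) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

place_chromocenters <- function(config, n_cc, r_eff, R) {
  rnl <- config$nucleolus_radius
  margin_base <- if (config$configuration == "NSN") 1.2 else 0.8
  margin <- margin_base
  sep_ok <- function(c_new, r_new, centers, radii) {
    if (nrow(centers) == 0) return(TRUE)
    dd <- sqrt(rowSums(sweep(centers, 2, c_new)^2))
    all(dd >= (r_new + radii) + margin)
  }
  for (attempt in seq_len(25)) {
    # relax the separation margin on late restarts rather than failing a
    # crowded draw outright; merging risk rises only for those nuclei
    margin <- margin_base *
      if (attempt > 22) 0.35 else if (attempt > 18) 0.55 else
      if (attempt > 10) 0.8 else 1
    centers <- matrix(numeric(0), 0, 3)
    ok <- TRUE
    for (i in seq_len(n_cc)) {
      placed <- FALSE
      for (try in seq_len(600)) {
        if (config$configuration == "NSN") {
          u <- random_unit()
          rad <- max(R - r_eff[i] - 0.3, 0.1) * runif(1)^(1 / 3)
          cand <- as.numeric(u) * rad
          # keep clear of the nucleolus when the nucleus has room for it;
          # lognormal-tail giants are allowed to touch it instead of
          # failing generation
          nl_clear <- rnl + r_eff[i] + 0.4 <= R - r_eff[i] - 0.35
          if (nl_clear && sqrt(sum(cand^2)) < rnl + r_eff[i] + 0.4) next
        } else {
          u <- as.numeric(random_unit())
          cand <- u * (rnl + 0.75 * r_eff[i])
          if (sqrt(sum(cand^2)) + r_eff[i] > R - 0.3) next
        }
        if (sep_ok(cand, r_eff[i], centers, if (i > 1) r_eff[seq_len(i - 1)]
                   else numeric(0))) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      colnames(centers) <- c("y", "x", "z")
      return(list(centers = centers))
    }
  }
  stop(sprintf(
    "could not place %d chromocenters (config: %s, nucleus %.1f um, seed %d)",
    n_cc, config$configuration, R, config$seed))
}

place_fragments <- function(config, cc_centers, r_eff, R) {
  out <- matrix(numeric(0), 0, 3)
  for (i in seq_len(config$n_fragments)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      u <- as.numeric(random_unit())
      cand <- u * (R - 1.0) * runif(1)^(1 / 3)
      if (sqrt(sum(cand^2)) < config$nucleolus_radius + 0.8) next
      dd <- sqrt(rowSums(sweep(cc_centers, 2, cand)^2))
      if (all(dd >= r_eff + 2.2)) {
        out <- rbind(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place fragment %d (seed %d)", i, config$seed))
  }
  colnames(out) <- c("y", "x", "z")
  out
}

make_fiber_kernels <- function(config, r_base, anis) {
  k <- sample(seq(config$n_fibers_range[1], config$n_fibers_range[2]), 1)
  semi <- 0.85 * r_base * anis
  pos <- matrix(0, k, 3)
  for (j in seq_len(k)) {
    repeat {
      p <- runif(3, -1, 1)
      if (sum(p^2) <= 1) break
    }
    pos[j, ] <- p * semi
  }
  list(pos = pos, dir = random_unit(k),
       sigma_long = max(0.35 * r_base, config$fiber_sigma),
       sigma_perp = config$fiber_sigma)
}

# Evaluate the fiber-kernel field at physical (y, x, z) coords relative to
# the object centre; positions optionally scaled by the distension factor.
# Distension scales kernel positions (fiber-fiber spacing) by `distension`
# and the transverse bundle width by sqrt(distension); each kernel is an
# anisotropic Gaussian with an explicitly normalized mass
# (~ sigma_long * sigma_perp^2, independent of distension), so integrated
# intensity is conserved exactly. The voxel box variance (h^2/12 per axis)
# is folded into the covariance so the discrete voxel sum matches the
# continuous integral even when fibers are thinner than a voxel.
field_values <- function(coords, kern, distension = 1, vs) {
  val <- numeric(nrow(coords))
  sl <- kern$sigma_long
  sp <- kern$sigma_perp * sqrt(distension)
  mass <- kern$sigma_long * kern$sigma_perp^2 * 1e3  # arbitrary unit scale
  box <- diag(c(vs[["y"]], vs[["x"]], vs[["z"]])^2 / 12)
  for (j in seq_len(nrow(kern$pos))) {
    d3 <- kern$dir[j, ]
    Sig <- sl^2 * tcrossprod(d3) + sp^2 * (diag(3) - tcrossprod(d3)) + box
    A <- solve(Sig)
    delta <- sweep(coords, 2, kern$pos[j, ] * distension)
    q <- A[1, 1] * delta[, 1]^2 + A[2, 2] * delta[, 2]^2 +
      A[3, 3] * delta[, 3]^2 +
      2 * (A[1, 2] * delta[, 1] * delta[, 2] +
             A[1, 3] * delta[, 1] * delta[, 3] +
             A[2, 3] * delta[, 2] * delta[, 3])
    raw <- exp(-0.5 * q)
    # each kernel's voxelized field carries exactly `mass` total
    # intensity, so distension conserves the integral to float precision
    val <- val + raw * (mass / sum(raw))
  }
  val
}

# Render one object into a local subgrid. The intensity scale is chosen so
# that, at distension 1, the level set {background + field > threshold_ref}
# has exactly `target_volume`; the same scale is reused for the distended
# field so distension conserves integrated intensity.
render_object <- function(dims, vs, ctr, kern, distension, target_volume,
                          headroom, psf_sigma = 0) {
  extent <- max(abs(kern$pos)) * distension + 4 * kern$sigma_long +
    4 * psf_sigma + 0.2
  iy <- index_window(ctr[["y"]], extent, vs[["y"]], dims[1])
  ix <- index_window(ctr[["x"]], extent, vs[["x"]], dims[2])
  iz <- index_window(ctr[["z"]], extent, vs[["z"]], dims[3])
  ys <- (iy - 0.5) * vs[["y"]] - ctr[["y"]]
  xs <- (ix - 0.5) * vs[["x"]] - ctr[["x"]]
  zs <- (iz - 0.5) * vs[["z"]] - ctr[["z"]]
  coords <- cbind(rep(ys, times = length(ix) * length(iz)),
                  rep(rep(xs, each = length(iy)), times = length(iz)),
                  rep(zs, each = length(iy) * length(ix)))
  voxvol <- prod(vs)
  f1 <- field_values(coords, kern, 1, vs)
  sub_dim <- c(length(iy), length(ix), length(iz))
  # calibrate on the field as it will look after the acquisition PSF, so
  # the post-blur threshold-level set encloses exactly target_volume
  f1cal <- f1
  if (psf_sigma > 0)
    f1cal <- as.numeric(blur3d_cpp(array(f1, dim = sub_dim), sub_dim,
                                   psf_sigma / vs[c("y", "x", "z")]))
  m <- max(1L, round(target_volume / voxvol))
  if (m > length(f1cal)) m <- length(f1cal)
  cc <- sort(f1cal, decreasing = TRUE)[m]
  scale <- headroom / cc
  fd <- if (distension > 1) field_values(coords, kern, distension, vs)
        else f1
  vals <- scale * fd
  list(iy = iy, ix = ix, iz = iz,
       values = array(vals, dim = sub_dim),
       integral = sum(vals))
}

index_window <- function(center_um, extent_um, vs1, n) {
  i0 <- max(1L, floor((center_um - extent_um) / vs1))
  i1 <- min(n, ceiling((center_um + extent_um) / vs1))
  seq(i0, i1)
}

add_subfield <- function(arr, ob) {
  arr[ob$iy, ob$ix, ob$iz] <- arr[ob$iy, ob$ix, ob$iz] + ob$values
  arr
}

apply_noise <- function(arr, config) {
  d <- dim(arr)
  v <- as.numeric(arr)
  if (config$poisson_scale > 0)
    v <- rpois(length(v), v / config$poisson_scale) * config$poisson_scale
  if (config$gaussian_sd > 0)
    v <- v + rnorm(length(v), 0, config$gaussian_sd)
  array(pmin(pmax(round(v), 0), 65535), dim = d)
}
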
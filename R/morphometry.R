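#' Classify nuclear configuration (NSN vs SN) from nucleolar contact
#'
#' A nucleus is called SN ("surrounded nucleolus") when more than
#' `contact_fraction` of its chromocenters lie within `contact_distance` of
#' the nucleolar surface (surface-to-surface, i.e. the closest region voxel
#' to the nucleolar sphere), NSN otherwise. This operationalizes the
#' qualitative description that in SN oocytes most chromocenters become
#' associated with the nucleolus.
#'
#' @param regions list of `chromocenter_region` objects.
#' @param nucleolus either a list `list(center_um =, radius_um =)` (sphere)
#'   or a logical mask array of the same dimensions as the stack.
#' @param contact_distance µm, default 0.2.
#' @param contact_fraction decision threshold, default 0.5.
#' @param stack the [image_stack()] the regions came from (needed to
#'   convert a mask nucleolus into coordinates).
#' @return `"SN"`, `"NSN"`, or `"unknown"` (with a warning) when there are
#'   no regions; the fraction in contact is attached as attribute
#'   `"contact_fraction"`.
#' @export
classify_configuration <- function(regions, nucleolus,
                                   contact_distance = 0.2,
                                   contact_fraction = 0.5,
                                   stack = NULL) {
  stopifnot(contact_distance >= 0)
  if (length(regions) == 0) {
    warning("no chromocenter regions; configuration unknown")
    return(structure("unknown", contact_fraction = NA_real_))
  }
  dists <- vapply(regions, function(r)
    region_nucleolus_distance(r, nucleolus, stack), 0)
  frac <- mean(dists <= contact_distance)
  structure(if (frac > contact_fraction) "SN" else "NSN",
            contact_fraction = frac)
}

region_nucleolus_distance <- function(region, nucleolus, stack = NULL) {
  if (is.list(nucleolus) && !is.null(nucleolus$radius_um)) {
    ctr <- unlist(nucleolus$center_um)[c("y", "x", "z")]
    if (is.null(stack))
      stop("`stack` is required to locate region voxels")
    coords <- voxel_coords_um(region$voxels, stack_dim(stack),
                              stack$voxel_size)
    dd <- sqrt(colSums((t(coords) - ctr)^2)) - nucleolus$radius_um
    max(min(dd), 0)
  } else if (is.array(nucleolus)) {
    if (!any(nucleolus)) stop("nucleolus mask is empty")
    if (is.null(stack)) stop("`stack` is required with a mask nucleolus")
    vs <- stack$voxel_size
    dims <- dim(nucleolus)
    nl <- voxel_coords_um(which(nucleolus), dims, vs)
    coords <- voxel_coords_um(region$voxels, stack_dim(stack), vs)
    # min pairwise distance, chunked to bound memory
    best <- Inf
    for (a in seq_len(nrow(coords))) {
      dd <- sqrt((nl[, 1] - coords[a, 1])^2 + (nl[, 2] - coords[a, 2])^2 +
                   (nl[, 3] - coords[a, 3])^2)
      best <- min(best, min(dd))
    }
    best
  } else stop("`nucleolus` must be a sphere spec or a mask array")
}

#' Intensity line profile with peak detection
#'
#' Samples the channel along the segment `p0 -> p1` (physical µm, named
#' `c(y=, x=, z=)`) by trilinear interpolation at the given step, then finds
#' local maxima whose topographic prominence exceeds `prominence`. Ties in
#' peak detection are broken toward the lower coordinate. Nearest-neighbour
#' peak spacings estimate the fiber-to-fiber distance across a
#' chromocenter.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param p0,p1 segment endpoints, µm, inside the stack.
#' @param step sampling step, µm; default half the smallest voxel size.
#' @param prominence minimum peak prominence in intensity units; default
#'   10% of the profile's dynamic range.
#' @return list with `distance` (µm along the segment), `intensity`,
#'   `peaks` (data.frame: position_um, value, prominence) and `spacings`
#'   (successive peak-to-peak distances, µm).
#' @export
line_profile <- function(stack, channel, p0, p1, step = NULL,
                         prominence = NULL) {
  arr <- get_channel(stack, channel)
  vs <- stack$voxel_size
  dims <- dim(arr)
  p0 <- p0[c("y", "x", "z")]; p1 <- p1[c("y", "x", "z")]
  if (any(is.na(p0)) || any(is.na(p1)))
    stop("p0 and p1 must be named c(y=, x=, z=) vectors")
  if (all(p0 == p1)) stop("p0 and p1 must differ")
  lims <- c(dims[1] * vs[["y"]], dims[2] * vs[["x"]], dims[3] * vs[["z"]])
  if (any(p0 < 0 | p1 < 0) || any(p0 > lims | p1 > lims))
    stop("segment endpoints outside the stack")
  if (is.null(step)) step <- min(vs) / 2
  len <- sqrt(sum((p1 - p0)^2))
  tt <- seq(0, len, by = step)
  u <- (p1 - p0) / len
  pts_um <- cbind(p0[["y"]] + tt * u[["y"]],
                  p0[["x"]] + tt * u[["x"]],
                  p0[["z"]] + tt * u[["z"]])
  pts_vox <- cbind(pts_um[, 1] / vs[["y"]] + 0.5,
                   pts_um[, 2] / vs[["x"]] + 0.5,
                   pts_um[, 3] / vs[["z"]] + 0.5)
  inten <- trilinear_cpp(arr, dims, pts_vox)
  if (is.null(prominence)) prominence <- 0.1 * diff(range(inten))
  pk <- find_peaks(inten, prominence)
  peaks <- data.frame(position_um = tt[pk$idx], value = inten[pk$idx],
                      prominence = pk$prom)
  list(distance = tt, intensity = inten, peaks = peaks,
       spacings = diff(peaks$position_um))
}

# local maxima with topographic prominence; plateaus credited to the
# lowest-index sample (ties broken toward the lower coordinate)
find_peaks <- function(v, min_prominence) {
  n <- length(v)
  if (n < 3 || diff(range(v)) == 0)
    return(list(idx = integer(0), prom = numeric(0)))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0) return(list(idx = integer(0), prom = numeric(0)))
  prom <- vapply(cand, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1L)]
    right <- v[seq(p + 1L, n)]
    lmin <- min_before_higher(rev(left), h)
    rmin <- min_before_higher(right, h)
    h - max(lmin, rmin)
  }, 0)
  keep <- prom >= min_prominence
  list(idx = cand[keep], prom = prom[keep])
}

min_before_higher <- function(side, h) {
  higher <- which(side > h)
  if (length(higher) == 0) min(side) else min(side[seq_len(higher[1])])
}

#' Detect extrachromosomal satellite DNA fragments
#'
#' Segments the satellite channel with fragment-specific parameters (no
#' minimum volume, a maximum volume cap) and keeps components whose volume
#' is below the cap and whose centroid lies farther than `min_separation`
#' from every chromocenter surface (centroid-to-nearest-chromocenter-voxel,
#' robust to fragment shape).
#'
#' @param stack an [image_stack()].
#' @param chromocenters list of `chromocenter_region` from the main
#'   segmentation.
#' @param channel satellite channel name.
#' @param max_volume volume cap, µm³ (default the chromocenter minimum,
#'   2.30).
#' @param min_separation µm (default 1.0).
#' @param params segmentation parameters for the satellite channel; the
#'   min-volume filter is overridden to a two-voxel floor.
#' @return list of `chromocenter_region` objects for the fragments.
#' @export
detect_ec_fragments <- function(stack, chromocenters,
                                channel = "satellite",
                                max_volume = 2.30, min_separation = 1.0,
                                params = segmentation_params()) {
  if (!channel %in% names(stack$channels))
    stop(sprintf("no '%s' channel in stack", channel))
  voxvol <- voxel_volume(stack)
  p <- params
  p$min_volume <- 2 * voxvol  # no biological minimum, just a speckle floor
  cands <- segment_chromocenters(stack, channel = channel, params = p)
  cands <- Filter(function(r) r$volume <= max_volume, cands)
  if (length(cands) == 0 || length(chromocenters) == 0) return(cands)
  dims <- stack_dim(stack)
  vs <- stack$voxel_size
  cc_coords <- do.call(rbind, lapply(chromocenters, function(r)
    voxel_coords_um(r$voxels, dims, vs)))
  Filter(function(r) {
    dd <- sqrt((cc_coords[, 1] - r$centroid[["y"]])^2 +
                 (cc_coords[, 2] - r$centroid[["x"]])^2 +
                 (cc_coords[, 3] - r$centroid[["z"]])^2)
    min(dd) > min_separation
  }, cands)
}

#' Prevalence of fragment-positive nuclei
#'
#' @param fragment_counts integer vector, one entry per nucleus.
#' @return list with `n_positive`, `n_total` and `prevalence_pct`
#'   (percentage of nuclei with at least one fragment).
#' @export
ec_prevalence <- function(fragment_counts) {
  if (length(fragment_counts) == 0) stop("no nuclei")
  pos <- sum(fragment_counts >= 1)
  list(n_positive = pos, n_total = length(fragment_counts),
       prevalence_pct = 100 * pos / length(fragment_counts))
}

#' Per-nucleus morphometry record
#'
#' @param regions chromocenter regions of one nucleus.
#' @param id nucleus identifier.
#' @param configuration `"NSN"`, `"SN"` or `"unknown"`.
#' @param ec_fragment_count number of extrachromosomal fragments detected.
#' @return object of class `nucleus_morphometry`.
#' @export
nucleus_morphometry <- function(regions, id = 1L,
                                configuration = "unknown",
                                ec_fragment_count = 0L) {
  volumes <- vapply(regions, function(r) r$volume, 0)
  structure(list(
    id = id,
    configuration = configuration,
    chromocenter_count = length(regions),
    volumes = volumes,
    mean_volume = if (length(volumes)) mean(volumes) else NA_real_,
    mean_sphericity = if (length(regions))
      mean(vapply(regions, function(r) r$sphericity, 0)) else NA_real_,
    ec_fragment_count = ec_fragment_count
  ), class = "nucleus_morphometry")
}

#' Cohort summaries of nucleus morphometry
#'
#' Per-group means, SDs, n and box-plot five-number summaries for
#' chromocenter counts, volumes (pooled over chromocenters) and sphericity.
#' Groups with a single nucleus are flagged (`sd_undefined`).
#'
#' @param morphs list of `nucleus_morphometry`.
#' @param groups character vector of group labels, one per nucleus.
#' @return list with `summary` (data.frame) and `five_number` (per group,
#'   per metric).
#' @export
summarize_cohort <- function(morphs, groups) {
  if (length(morphs) != length(groups))
    stop("`groups` must have one label per nucleus")
  if (any(is.na(groups) | groups == ""))
    stop("unknown group label")
  glev <- unique(groups)
  rows <- list(); fives <- list()
  for (g in glev) {
    sel <- morphs[groups == g]
    counts <- vapply(sel, function(m) m$chromocenter_count, 0)
    vols <- unlist(lapply(sel, function(m) m$volumes))
    sph <- vapply(sel, function(m) m$mean_sphericity, 0)
    rows[[g]] <- data.frame(
      group = g, n_nuclei = length(sel),
      mean_count = mean(counts),
      sd_count = if (length(sel) > 1) sd(counts) else NA_real_,
      mean_volume_um3 = if (length(vols)) mean(vols) else NA_real_,
      sd_volume_um3 = if (length(vols) > 1) sd(vols) else NA_real_,
      mean_sphericity = mean(sph, na.rm = TRUE),
      sd_undefined = length(sel) < 2
    )
    fives[[g]] <- list(count = five_number(counts),
                       volume_um3 = if (length(vols)) five_number(vols)
                                    else NULL,
                       sphericity = five_number(sph))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       five_number = fives)
}

#' Maximum-intensity projection of a stack channel
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return 2D matrix (y, x) of per-column maxima along z.
#' @export
max_intensity_projection <- function(stack, channel = "dapi") {
  arr <- get_channel(stack, channel)
  apply(arr, c(1, 2), max)
}

#' Segment a maximum-intensity projection (projected-area mode)
#'
#' Mirrors projection-based quantification workflows: smoothing,
#' threshold and connected components on the 2D projection. Results are
#' PROJECTED AREAS in µm² (column `area_um2`), deliberately labelled so
#' they are never mixed with full-3D volumes; full-3D segmentation via
#' [segment_chromocenters()] is the package default.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param params a [segmentation_params()]; `min_volume` is reinterpreted
#'   as a minimum projected area in µm².
#' @return data.frame with id, area_um2, centroid_y_um, centroid_x_um.
#' @export
segment_projection <- function(stack, channel = "dapi",
                               params = segmentation_params()) {
  mip <- max_intensity_projection(stack, channel)
  vs <- stack$voxel_size
  d3 <- c(dim(mip), 1L)
  sm <- array(mip, dim = d3)
  if (params$smoothing_scale > 0) {
    sig <- c(params$smoothing_scale / vs[c("y", "x")], 0)
    if (any(sig >= 0.05)) sm <- blur3d_cpp(sm, d3, sig)
  }
  thr <- if (params$threshold_mode == "absolute") params$intensity_threshold
         else params$relative_fraction * quantile(sm, 0.999, names = FALSE)
  lab <- label3d_cpp(sm > thr, d3, params$connectivity)
  px_area <- vs[["y"]] * vs[["x"]]
  idx <- which(lab > 0L)
  if (length(idx) == 0)
    return(data.frame(id = integer(0), area_um2 = numeric(0),
                      centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0)))
  parts <- split(idx, lab[idx])
  keep <- parts[vapply(parts, length, 1L) * px_area >= params$min_volume]
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    v <- keep[[i]]
    iy <- ((v - 1L) %% d3[1]) + 1L
    jx <- ((v - 1L) %/% d3[1]) + 1L
    data.frame(id = i, area_um2 = length(v) * px_area,
               centroid_y_um = mean((iy - 0.5) * vs[["y"]]),
               centroid_x_um = mean((jx - 0.5) * vs[["x"]]))
  }))
  out[order(-out$area_um2), , drop = FALSE]
}
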
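#' Configuration for simulated chromocenter motion
#'
#' Trajectories are sampled every `sampling_interval` seconds over
#' `duration` seconds (defaults: 5 min over 5 h, the live-imaging
#' schedule). Step lengths are drawn from a Rayleigh distribution scaled so
#' that the expected mean speed (total path / duration) equals
#' `target_mean_speed`. Regimes differ only in step directions, so the
#' speed calibration holds for all of them:
#' \describe{
#'   \item{anchored_oscillatory}{random directions, positions confined
#'     within `confinement_radius` of a per-track anchor (directions are
#'     resampled when a step would leave the shell, preserving step
#'     length); models chromocenters oscillating at the nucleolus.}
#'   \item{detached_directed}{each step direction mixes a persistent
#'     per-track drift direction (weight `directed_fraction`) with an
#'     isotropic random direction; models post-irradiation linear
#'     displacement after nucleolar detachment.}
#'   \item{senescent_directed}{same kinematics as `detached_directed`,
#'     kept as a separate regime label for senescent oocytes.}
#' }
#'
#' @param regime one of `"anchored_oscillatory"`, `"detached_directed"`,
#'   `"senescent_directed"`.
#' @param target_mean_speed µm/s, > 0.
#' @param confinement_radius µm (oscillatory regime only).
#' @param directed_fraction in \[0, 1\] (directed regimes).
#' @param sampling_interval s, default 300.
#' @param duration s, default 18000; must be a multiple of the interval.
#' @param n_tracks number of trajectories.
#' @param tracks_per_nucleus tracks are grouped into synthetic nuclei of
#'   this size (anchors separated within a nucleus), mirroring multi-oocyte
#'   acquisitions.
#' @param seed integer RNG seed.
#' @return object of class `motion_config`.
#' @export
motion_config <- function(regime = c("anchored_oscillatory",
                                     "detached_directed",
                                     "senescent_directed"),
                          target_mean_speed = 0.003,
                          confinement_radius = 2,
                          directed_fraction = 0.6,
                          sampling_interval = 300,
                          duration = 18000,
                          n_tracks = 60,
                          tracks_per_nucleus = 6,
                          seed = 1) {
  regime <- match.arg(regime)
  stopifnot(target_mean_speed > 0, confinement_radius > 0,
            directed_fraction >= 0, directed_fraction <= 1,
            sampling_interval > 0, duration > 0, n_tracks >= 1)
  if (duration %% sampling_interval != 0)
    stop("duration must be a multiple of sampling_interval")
  structure(list(regime = regime,
                 target_mean_speed = target_mean_speed,
                 confinement_radius = confinement_radius,
                 directed_fraction = directed_fraction,
                 sampling_interval = sampling_interval,
                 duration = duration,
                 n_tracks = as.integer(n_tracks),
                 tracks_per_nucleus = as.integer(tracks_per_nucleus),
                 seed = as.integer(seed)),
            class = "motion_config")
}

#' Generate a simulated chromocenter track set
#'
#' @param config a [motion_config()].
#' @return list with `tracks` (data.frame: track_id, frame, t_seconds,
#'   x_um, y_um, z_um, group, nucleus_id) and `ground_truth` (per-track
#'   true step series, anchors and drift directions).
#' @export
gen_trackset <- function(config) {
  stopifnot(inherits(config, "motion_config"))
  set.seed(config$seed)
  n_steps <- config$duration %/% config$sampling_interval
  sigma <- config$target_mean_speed * config$sampling_interval /
    sqrt(pi / 2)  # Rayleigh: E[L] = sigma * sqrt(pi/2)
  rows <- vector("list", config$n_tracks)
  gt_steps <- vector("list", config$n_tracks)
  anchors <- matrix(0, config$n_tracks, 3)
  drifts <- matrix(NA_real_, config$n_tracks, 3)

  for (tr in seq_len(config$n_tracks)) {
    nucleus <- (tr - 1L) %/% config$tracks_per_nucleus + 1L
    slot <- (tr - 1L) %% config$tracks_per_nucleus
    # anchors on a coarse grid within each synthetic nucleus, nuclei 40 um
    # apart, so tracks are unambiguous for linking
    base <- c(40 * nucleus, 8 * (slot %% 3), 8 * (slot %/% 3))
    anchor <- base + runif(3, -1, 1)
    anchors[tr, ] <- anchor
    L <- sigma * sqrt(-2 * log(runif(n_steps)))  # Rayleigh lengths
    gt_steps[[tr]] <- L
    pos <- matrix(0, n_steps + 1L, 3)
    pos[1, ] <- anchor
    if (config$regime == "anchored_oscillatory") {
      Rc <- config$confinement_radius
      for (s in seq_len(n_steps)) {
        dvec <- pos[s, ] - anchor
        dist <- sqrt(sum(dvec^2))
        if (L[s] > dist + Rc) {
          # step longer than any in-shell landing allows (rare Rayleigh
          # tail); land on the shell, shortening this one step
          cand <- anchor + Rc * as.numeric(random_unit())
        } else {
          cand <- NULL
          for (try in seq_len(200)) {
            u <- as.numeric(random_unit())
            p <- pos[s, ] + L[s] * u
            if (sqrt(sum((p - anchor)^2)) <= Rc) { cand <- p; break }
          }
          if (is.null(cand)) {
            # exact fallback preserving step length: stepping straight
            # toward the anchor always lands inside when L <= dist + Rc
            u <- if (dist > 0) -dvec / dist else as.numeric(random_unit())
            cand <- pos[s, ] + L[s] * u
          }
        }
        pos[s + 1L, ] <- cand
      }
    } else {
      drift <- as.numeric(random_unit())
      drifts[tr, ] <- drift
      f <- config$directed_fraction
      for (s in seq_len(n_steps)) {
        mix <- f * drift + (1 - f) * as.numeric(random_unit())
        u <- mix / sqrt(sum(mix^2))
        pos[s + 1L, ] <- pos[s, ] + L[s] * u
      }
    }
    rows[[tr]] <- data.frame(
      track_id = tr,
      frame = 0:n_steps,
      t_seconds = (0:n_steps) * config$sampling_interval,
      x_um = pos[, 2], y_um = pos[, 1], z_um = pos[, 3],
      group = config$regime,
      nucleus_id = nucleus
    )
  }
  tracks <- do.call(rbind, rows)
  gt <- list(regime = config$regime,
             target_mean_speed = config$target_mean_speed,
             expected_path_um = config$target_mean_speed * config$duration,
             step_series = gt_steps,
             anchors = anchors,
             drift_directions = drifts,
             seed = config$seed)
  list(tracks = tracks, ground_truth = gt)
}
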
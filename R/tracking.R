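#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-pair assignment between consecutive frames:
#' among all (active track head, new detection) pairs the smallest
#' distance is linked first, then the next smallest among the remaining,
#' until distances exceed `max_displacement`. Unmatched detections start
#' new tracks; a track that is not extended at a frame ends (no gap
#' closing). Ties are broken toward the lower track id. If the table has
#' a `nucleus_id` column, linking is performed within each nucleus.
#'
#' @param detections data.frame with columns `frame`, `t_seconds`,
#'   `x_um`, `y_um`, `z_um` and optionally `nucleus_id`, `group`.
#' @param max_displacement µm; larger frame-to-frame jumps are not linked
#'   (default 3 µm per 5-min interval, roughly ten times the irradiated
#'   mean step).
#' @return data.frame like `detections` plus a `track_id` column.
#' @export
link_tracks <- function(detections, max_displacement = 3) {
  stopifnot(max_displacement > 0)
  req <- c("frame", "t_seconds", "x_um", "y_um", "z_um")
  if (!all(req %in% names(detections)))
    stop("detections must have columns: ", paste(req, collapse = ", "))
  if (!all(is.finite(as.matrix(detections[, c("x_um", "y_um", "z_um")]))))
    stop("coordinates must be finite")
  key <- do.call(paste, c(detections[, c("frame", "x_um", "y_um", "z_um")],
                          sep = "|"))
  if (anyDuplicated(key)) stop("duplicate (frame, position) rows")

  if ("nucleus_id" %in% names(detections)) {
    parts <- split(detections, detections$nucleus_id)
    offset <- 0L
    out <- lapply(parts, function(p) {
      r <- link_tracks_one(p, max_displacement)
      r$track_id <- r$track_id + offset
      offset <<- max(r$track_id)
      r
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }
  link_tracks_one(detections, max_displacement)
}

link_tracks_one <- function(det, max_disp) {
  det <- det[order(det$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  next_id <- 1L
  prev_rows <- integer(0)  # row indices of track heads in previous frame
  for (f in frames) {
    cur_rows <- which(det$frame == f)
    if (length(prev_rows) > 0 && length(cur_rows) > 0) {
      A <- as.matrix(det[prev_rows, c("x_um", "y_um", "z_um")])
      B <- as.matrix(det[cur_rows, c("x_um", "y_um", "z_um")])
      D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      D <- sqrt(pmax(D, 0))
      free_a <- rep(TRUE, nrow(D)); free_b <- rep(TRUE, ncol(D))
      # order pairs by distance; ties toward the lower track id
      ids_a <- det$track_id[prev_rows]
      ord <- order(as.numeric(D), rep(ids_a, times = ncol(D)))
      for (p in ord) {
        if (D[p] > max_disp) break
        a <- ((p - 1L) %% nrow(D)) + 1L
        b <- ((p - 1L) %/% nrow(D)) + 1L
        if (free_a[a] && free_b[b]) {
          det$track_id[cur_rows[b]] <- ids_a[a]
          free_a[a] <- FALSE; free_b[b] <- FALSE
        }
      }
    }
    new_b <- cur_rows[is.na(det$track_id[cur_rows])]
    for (b in new_b) {
      det$track_id[b] <- next_id
      next_id <- next_id + 1L
    }
    prev_rows <- cur_rows
  }
  rownames(det) <- NULL
  det
}

#' Per-track mobility metrics
#'
#' Path length is the sum of consecutive Euclidean step lengths; mean
#' speed is total path over elapsed time (the definition consistent with
#' published paired speed/path values: speed x 5 h = path);
#' straightness is net displacement over path length.
#'
#' @param track data.frame of one track (columns `t_seconds`, `x_um`,
#'   `y_um`, `z_um`), rows in frame order.
#' @return data.frame row: n_frames, duration_s, path_um, speed_um_per_s,
#'   net_displacement_um, straightness, degenerate (TRUE for
#'   single-detection tracks, whose metrics are zero).
#' @export
track_metrics <- function(track) {
  n <- nrow(track)
  if (n < 1) stop("empty track")
  if (n == 1) {
    return(data.frame(n_frames = 1L, duration_s = 0, path_um = 0,
                      speed_um_per_s = 0, net_displacement_um = 0,
                      straightness = NA_real_, degenerate = TRUE))
  }
  P <- as.matrix(track[, c("x_um", "y_um", "z_um")])
  steps <- sqrt(rowSums(diff(P)^2))
  path <- sum(steps)
  dur <- track$t_seconds[n] - track$t_seconds[1]
  net <- sqrt(sum((P[n, ] - P[1, ])^2))
  data.frame(n_frames = n, duration_s = dur, path_um = path,
             speed_um_per_s = if (dur > 0) path / dur else 0,
             net_displacement_um = net,
             straightness = if (path > 0) net / path else NA_real_,
             degenerate = FALSE)
}

#' Metrics for every track in a linked table
#'
#' @param tracks data.frame with `track_id` (from [link_tracks()] or a
#'   generator) and coordinate/time columns; an optional `group` column is
#'   carried through.
#' @return data.frame, one row per track.
#' @export
trackset_metrics <- function(tracks) {
  parts <- split(tracks, tracks$track_id)
  out <- do.call(rbind, lapply(names(parts), function(id) {
    p <- parts[[id]][order(parts[[id]]$frame), , drop = FALSE]
    m <- track_metrics(p)
    m$track_id <- as.integer(id)
    if ("group" %in% names(p)) m$group <- p$group[1]
    m
  }))
  rownames(out) <- NULL
  out
}

#' Group mobility summaries with ANOVA and Tukey HSD
#'
#' Per-group mean ± SD of speed and path length, plus a one-way ANOVA
#' across groups and all-pairs Tukey HSD (when there are at least three
#' groups with two or more tracks each; with exactly two groups a
#' two-sample comparison is reported instead). Groups with fewer than two
#' tracks are summarized but excluded from testing, with a warning.
#'
#' @param metrics data.frame from [trackset_metrics()] with a `group`
#'   column.
#' @return list with `summary` (per group), and `speed`/`path` test
#'   reports (each a [anova_tukey()] or [compare_two()] result, or NULL).
#' @export
cohort_mobility <- function(metrics) {
  if (!"group" %in% names(metrics)) stop("metrics must have a group column")
  groups <- unique(metrics$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    m <- metrics[metrics$group == g, ]
    data.frame(group = g, n_tracks = nrow(m),
               mean_speed_um_per_s = mean(m$speed_um_per_s),
               sd_speed_um_per_s = if (nrow(m) > 1) sd(m$speed_um_per_s)
                                   else NA_real_,
               mean_path_um = mean(m$path_um),
               sd_path_um = if (nrow(m) > 1) sd(m$path_um) else NA_real_)
  }))
  testable <- groups[vapply(groups, function(g)
    sum(metrics$group == g) >= 2, TRUE)]
  dropped <- setdiff(groups, testable)
  if (length(dropped) > 0)
    warning("groups with < 2 tracks excluded from testing: ",
            paste(dropped, collapse = ", "))
  test_on <- function(values, glab) {
    sel <- glab %in% testable
    v <- values[sel]; g <- glab[sel]
    if (length(unique(g)) >= 3) anova_tukey(v, g)
    else if (length(unique(g)) == 2) {
      gs <- unique(g)
      compare_two(v[g == gs[1]], v[g == gs[2]], method = "t")
    } else NULL
  }
  list(summary = summ,
       speed = test_on(metrics$speed_um_per_s, metrics$group),
       path = test_on(metrics$path_um, metrics$group))
}
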
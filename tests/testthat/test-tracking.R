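mk_det <- function(pos_list) {
  # pos_list: list of per-frame m x 3 matrices (x, y, z)
  do.call(rbind, lapply(seq_along(pos_list), function(f) {
    p <- pos_list[[f]]
    data.frame(frame = f - 1L, t_seconds = (f - 1) * 300,
               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  }))
}

test_that("single mover yields one track over all frames", {
  det <- mk_det(lapply(0:10, function(f) matrix(c(f * 0.1, 0, 0), 1)))
  tr <- link_tracks(det, 3)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 11)
})

test_that("greedy linking matches exhaustive assignment on small cases", {
  # two movers whose cross-distances always exceed max_displacement
  set.seed(4)
  a <- t(vapply(0:8, function(f) c(f * 0.2, 0, 0), numeric(3)))
  b <- t(vapply(0:8, function(f) c(f * 0.2, 10, 0), numeric(3)))
  det <- mk_det(lapply(1:9, function(f) rbind(a[f, ], b[f, ])))
  tr <- link_tracks(det, 3)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    yy <- tr$y_um[tr$track_id == id]
    expect_equal(length(unique(yy)), 1)  # never swaps between movers
  }
  # exhaustive oracle on 3 objects x 2 frames: minimize total distance
  # over all permutations and compare with the greedy result
  p0 <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  p1 <- p0 + matrix(c(0.1, 0, 0), 3, 3, byrow = TRUE)
  det2 <- mk_det(list(p0, p1))
  tr2 <- link_tracks(det2, 3)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  costs <- vapply(perms, function(pm)
    sum(sqrt(rowSums((p1[pm, ] - p0)^2))), 0)
  best <- perms[[which.min(costs)]]
  got <- tr2$track_id[tr2$frame == 1][order(tr2$x_um[tr2$frame == 1])]
  expect_equal(got, tr2$track_id[tr2$frame == 0][best])
})

test_that("jumps beyond max_displacement split tracks", {
  pos <- lapply(0:6, function(f)
    matrix(c(if (f < 3) f * 0.1 else 50 + f * 0.1, 0, 0), 1))
  tr <- link_tracks(mk_det(pos), 3)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("duplicate detections are rejected", {
  det <- mk_det(list(matrix(c(1, 1, 1), 1)))
  expect_error(link_tracks(rbind(det, det), 3), "duplicate")
})

test_that("track metrics follow their definitions", {
  # stationary track
  still <- data.frame(frame = 0:5, t_seconds = (0:5) * 300,
                      x_um = 1, y_um = 2, z_um = 3)
  m <- track_metrics(still)
  expect_equal(m$path_um, 0)
  expect_equal(m$speed_um_per_s, 0)
  # 60 steps of exactly 0.3 um at 300 s -> path 18 um, speed 0.001 um/s
  tr <- data.frame(frame = 0:60, t_seconds = (0:60) * 300,
                   x_um = (0:60) * 0.3, y_um = 0, z_um = 0)
  m2 <- track_metrics(tr)
  expect_equal(m2$path_um, 18)
  expect_equal(m2$speed_um_per_s, 0.001)
  expect_equal(m2$straightness, 1)
  # single detection: zero metrics, flagged
  m3 <- track_metrics(still[1, ])
  expect_true(m3$degenerate)
  expect_equal(m3$path_um, 0)
})

test_that("path length is rigid-motion invariant and decreases under subsampling", {
  set.seed(7)
  tr <- data.frame(frame = 0:40, t_seconds = (0:40) * 300,
                   x_um = cumsum(rnorm(41, 0, 0.3)),
                   y_um = cumsum(rnorm(41, 0, 0.3)),
                   z_um = cumsum(rnorm(41, 0, 0.3)))
  theta <- 0.7
  Rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- as.matrix(tr[, c("x_um", "y_um", "z_um")]) %*% t(Rz)
  tr2 <- tr; tr2[, c("x_um", "y_um", "z_um")] <- sweep(rot, 2, c(5, -2, 1),
                                                       "+")
  expect_equal(track_metrics(tr)$path_um, track_metrics(tr2)$path_um)
  sub <- tr[seq(1, 41, by = 2), ]
  expect_lte(track_metrics(sub)$path_um, track_metrics(tr)$path_um)
})

test_that("speed times duration reproduces path length exactly", {
  res <- gen_trackset(preset("ctrl_motion", seed = 2))
  m <- trackset_metrics(res$tracks)
  expect_equal(m$speed_um_per_s * m$duration_s, m$path_um,
               tolerance = 1e-12)
})

test_that("cohort mobility summarizes and tests across groups", {
  set.seed(5)
  mk <- function(g, mean_speed, n) data.frame(
    speed_um_per_s = rnorm(n, mean_speed, 0.0005),
    path_um = rnorm(n, mean_speed * 18000, 5), group = g)
  m <- rbind(mk("a", 0.003, 20), mk("b", 0.003, 20), mk("c", 0.006, 20))
  mob <- cohort_mobility(m)
  expect_equal(nrow(mob$summary), 3)
  pr <- mob$speed$pairs
  expect_gt(pr$p_adj[pr$pair == "b-a"], 0.05)
  expect_lt(pr$p_adj[pr$pair == "c-a"], 0.001)
  # three identical groups: omnibus F ~ 0, all pairs ns
  tmpl <- mk("a", 0.003, 15)
  m0 <- do.call(rbind, lapply(c("a", "b", "c"), function(g) {
    d <- tmpl; d$group <- g; d
  }))
  mob0 <- cohort_mobility(m0)
  expect_lt(mob0$speed$f_statistic, 1e-10)
  expect_true(all(mob0$speed$pairs$p_adj > 0.99))
  # undersized group is summarized but excluded from testing
  m2 <- rbind(mk("a", 0.003, 10), mk("b", 0.004, 10), mk("c", 0.005, 1))
  expect_warning(mob2 <- cohort_mobility(m2), "excluded")
  expect_equal(nrow(mob2$summary), 3)
  expect_identical(mob2$speed$test, "t")
})
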
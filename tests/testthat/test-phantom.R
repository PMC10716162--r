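test_that("phantom generation is a pure function of config and seed", {
  cfg <- fast_phantom_config(seed = 11)
  a <- gen_nucleus_phantom(cfg)
  b <- gen_nucleus_phantom(cfg)
  expect_identical(a$stack$channels$dapi, b$stack$channels$dapi)
  expect_identical(a$stack$channels$satellite, b$stack$channels$satellite)
  expect_identical(a$ground_truth, b$ground_truth)
  c3 <- gen_nucleus_phantom(fast_phantom_config(seed = 12))
  expect_false(identical(a$stack$channels$dapi, c3$stack$channels$dapi))
})

test_that("planted object counts are conserved in ground truth", {
  cfg <- fast_phantom_config(n_chromocenters_mean = 5,
                             n_chromocenters_sd = 0,
                             poisson_scale = 0, gaussian_sd = 0)
  ph <- gen_nucleus_phantom(cfg)
  expect_equal(ph$ground_truth$n_chromocenters, 5)
  expect_equal(nrow(ph$ground_truth$chromocenters), 5)
})

test_that("count draws are clipped to [1, 40] and volumes respect floor", {
  cfg <- fast_phantom_config(n_chromocenters_mean = 1,
                             n_chromocenters_sd = 4, seed = 3)
  for (s in 1:20) {
    cfg$seed <- s
    set.seed(s)
    n <- oochromatin:::draw_count(cfg)
    expect_gte(n, 1)
    expect_lte(n, 40)
  }
  set.seed(1)
  v <- oochromatin:::draw_volumes(fast_phantom_config(volume_mean = 4,
                                                      volume_sd = 4), 200)
  expect_true(all(v >= 2.533))
})

test_that("truncated lognormal moment matching hits requested moments", {
  p <- lognormal_params_for_mean_sd(6.04, 5.6, lower = 2.533)
  set.seed(42)
  v <- rlnorm(4e5, p["mu"], p["sigma"])
  v <- v[v >= 2.533]
  expect_equal(mean(v), 6.04, tolerance = 0.02)
  expect_equal(sd(v), 5.6, tolerance = 0.04)
  # untruncated closed form
  q <- lognormal_params_for_mean_sd(10, 5)
  expect_equal(exp(q["mu"] + q["sigma"]^2 / 2), c(mu = 10))
})

test_that("distension conserves integrated intensity and scales extent", {
  # a bright nucleoplasm keeps the rendered peaks inside the 16-bit
  # detector range, so the stack-sum oracle sees no saturation
  mk <- function(d) nucleus_phantom_config(
    nucleus_radius = 10, nucleolus_radius = 1, configuration = "NSN",
    n_chromocenters_mean = 1, n_chromocenters_sd = 0,
    volume_mean = 12, volume_sd = 0, distension_factor = d,
    voxel_size = c(x = 0.1, y = 0.1, z = 0.15), psf_sigma = 0.12,
    poisson_scale = 0, gaussian_sd = 0, background = 6000,
    n_fibers_range = c(8, 14), fiber_sigma = 0.3, seed = 7)
  p1 <- gen_nucleus_phantom(mk(1))
  p2 <- gen_nucleus_phantom(mk(2))
  i1 <- p1$ground_truth$chromocenters$integrated_intensity
  i2 <- p2$ground_truth$chromocenters$integrated_intensity
  expect_equal(i2 / i1, 1, tolerance = 0.01)
  # independent oracle: the two stacks share an identical noise-free
  # background (same geometry, same seed), so the total DAPI sums may
  # differ only by the change in object-integrated intensity
  expect_lt(max(p1$stack$channels$dapi), 65535)
  expect_lt(max(p2$stack$channels$dapi), 65535)
  s1 <- sum(p1$stack$channels$dapi)
  s2 <- sum(p2$stack$channels$dapi)
  expect_lt(abs(s2 - s1) / i1, 0.02)
  # ground-truth envelope volume scales by the cube of the linear factor
  env_vol <- function(p) with(p$ground_truth$chromocenters,
                              envelope_y_um * envelope_x_um * envelope_z_um)
  expect_equal(env_vol(p2) / env_vol(p1), 8, tolerance = 1e-9)
  # rendered occupied extent grows substantially (kernel size floors the
  # ratio below the pure-envelope factor of 8)
  bbox_vol <- function(p) {
    w <- which(p$stack$channels$satellite > 600, arr.ind = TRUE)
    prod(apply(w, 2, function(v) diff(range(v)) + 1))
  }
  expect_gt(bbox_vol(p2) / bbox_vol(p1), 2)
})

test_that("impossible placements raise a generation error naming the config", {
  cfg <- fast_phantom_config(nucleus_radius = 4, nucleolus_radius = 1.2,
                             n_chromocenters_mean = 30,
                             n_chromocenters_sd = 0,
                             volume_mean = 10, volume_sd = 0)
  expect_error(gen_nucleus_phantom(cfg), "could not place.*NSN")
})

test_that("config invariants are enforced", {
  expect_error(nucleus_phantom_config(nucleus_radius = 2,
                                      nucleolus_radius = 3),
               "nucleolus_radius")
  expect_error(nucleus_phantom_config(distension_factor = 0.5),
               "distension_factor")
  expect_error(nucleus_phantom_config(voxel_size = c(x = 0, y = 0.1,
                                                     z = 0.1)))
  expect_error(nucleus_phantom_config(volume_mean = 1, volume_sd = 1),
               "volume_mean")
})
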
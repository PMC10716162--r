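test_that("configuration classification follows the contact rule", {
  cfg <- fast_phantom_config(configuration = "SN", nucleolus_radius = 2,
                             n_chromocenters_mean = 6, volume_mean = 5,
                             volume_sd = 1, seed = 2)
  ph <- gen_nucleus_phantom(cfg)
  regs <- segment_chromocenters(ph$stack)
  cl <- classify_configuration(regs, ph$ground_truth$nucleolus,
                               stack = ph$stack)
  expect_identical(as.character(cl), "SN")
  expect_gt(attr(cl, "contact_fraction"), 0.5)

  cfg2 <- fast_phantom_config(configuration = "NSN", seed = 3)
  ph2 <- gen_nucleus_phantom(cfg2)
  regs2 <- segment_chromocenters(ph2$stack)
  cl2 <- classify_configuration(regs2, ph2$ground_truth$nucleolus,
                                stack = ph2$stack)
  expect_identical(as.character(cl2), "NSN")
  expect_warning(out <- classify_configuration(list(),
                                               ph2$ground_truth$nucleolus),
                 "unknown")
  expect_identical(as.character(out), "unknown")
})

test_that("classification accuracy on labelled phantoms is >= 95%", {
  n <- 25; correct <- 0
  for (s in seq_len(n)) for (conf in c("NSN", "SN")) {
    cfg <- fast_phantom_config(
      configuration = conf, nucleolus_radius = 3.0, nucleus_radius = 8,
      n_chromocenters_mean = if (conf == "NSN") 7.9 else 11.7,
      n_chromocenters_sd = 1.5,
      volume_mean = if (conf == "NSN") 9 else 5.5, volume_sd = 3,
      seed = s)
    ph <- gen_nucleus_phantom(cfg)
    cl <- classify_configuration(segment_chromocenters(ph$stack),
                                 ph$ground_truth$nucleolus,
                                 stack = ph$stack)
    correct <- correct + (as.character(cl) == conf)
  }
  expect_gte(correct / (2 * n), 0.95)
})

test_that("line profiles resolve planted fiber spacing", {
  # uniform stack: no peaks
  vs <- c(x = 0.04, y = 0.04, z = 0.08)
  flat <- image_stack(list(dapi = array(500, c(60, 120, 20))), vs)
  lp0 <- line_profile(flat, "dapi", c(y = 1, x = 0.5, z = 0.6),
                      c(y = 1, x = 4.0, z = 0.6))
  expect_equal(nrow(lp0$peaks), 0)
  # two parallel fibers 0.4 um apart, scanned perpendicular
  arr <- array(0, c(60, 120, 20))
  xs <- (seq_len(120) - 0.5) * vs[["x"]]
  for (x0 in c(2.0, 2.4)) {
    prof <- 4000 * exp(-(xs - x0)^2 / (2 * 0.05^2))
    for (i in 1:60) for (k in 8:12) arr[i, , k] <- arr[i, , k] + prof
  }
  st <- image_stack(list(dapi = arr), vs)
  lp <- line_profile(st, "dapi", c(y = 1.2, x = 0.8, z = 0.8),
                     c(y = 1.2, x = 3.6, z = 0.8))
  expect_equal(nrow(lp$peaks), 2)
  expect_equal(lp$spacings, 0.4, tolerance = vs[["x"]] / 0.4)
  # endpoints outside the stack are rejected
  expect_error(line_profile(st, "dapi", c(y = -1, x = 0, z = 0),
                            c(y = 1, x = 1, z = 1)), "outside")
})

test_that("distended chromocenters show wider fiber spacing in line scans", {
  # pooled nearest-neighbour peak spacings from a grid of parallel scans
  # across single-chromocenter phantoms, condensed vs 2x distended at
  # matched seeds
  scan_spacings <- function(d, seed) {
    cfg <- nucleus_phantom_config(
      nucleus_radius = 7, nucleolus_radius = 1, configuration = "NSN",
      n_chromocenters_mean = 1, n_chromocenters_sd = 0,
      volume_mean = 3, volume_sd = 0, distension_factor = d,
      n_fibers_range = c(6, 6), fiber_sigma = 0.07,
      voxel_size = c(x = 0.04, y = 0.04, z = 0.08), psf_sigma = 0.05,
      poisson_scale = 0, gaussian_sd = 0, seed = seed)
    ph <- gen_nucleus_phantom(cfg)
    dims <- dim(ph$stack$channels$satellite)
    vs <- ph$stack$voxel_size
    lim <- c(dims[1] * vs[["y"]], dims[2] * vs[["x"]], dims[3] * vs[["z"]])
    ctr <- unname(unlist(ph$ground_truth$chromocenters[
      1, c("y_um", "x_um", "z_um")]))
    half <- 1.8 * d
    sp <- numeric(0)
    for (off in seq(-0.2, 0.2, by = 0.1) * d)
      for (zoff in seq(-0.2, 0.2, by = 0.1) * d) {
        p0 <- c(y = ctr[1] + off, x = max(ctr[2] - half, 0.1),
                z = ctr[3] + zoff)
        p1 <- c(y = ctr[1] + off, x = min(ctr[2] + half, lim[2] - 0.1),
                z = ctr[3] + zoff)
        if (p0[["z"]] < 0.1 || p0[["z"]] > lim[3] - 0.1) next
        lp <- line_profile(ph$stack, "satellite", p0, p1)
        pr <- 0.05 * diff(range(lp$intensity))
        pk <- lp$peaks[lp$peaks$prominence >= pr, ]
        sp <- c(sp, diff(pk$position_um))
      }
    sp
  }
  s1 <- numeric(0); s2 <- numeric(0)
  for (seed in 1:6) {
    s1 <- c(s1, scan_spacings(1, seed))
    s2 <- c(s2, scan_spacings(2, seed))
  }
  expect_gte(length(s1), 10)
  expect_gte(length(s2), 10)
  expect_gt(mean(s2), mean(s1))
})

test_that("fragment detection recovers planted extrachromosomal satellites", {
  cfg <- fast_phantom_config(nucleus_radius = 8, n_fragments = 3,
                             poisson_scale = 0, gaussian_sd = 0, seed = 4)
  ph <- gen_nucleus_phantom(cfg)
  regs <- segment_chromocenters(ph$stack)
  fr <- detect_ec_fragments(ph$stack, regs)
  expect_length(fr, 3)
  expect_true(all(vapply(fr, function(r) r$volume, 0) <= 2.30))
  # no planted fragments -> none detected
  cfg0 <- fast_phantom_config(poisson_scale = 0, gaussian_sd = 0, seed = 4)
  ph0 <- gen_nucleus_phantom(cfg0)
  expect_length(detect_ec_fragments(ph0$stack,
                                    segment_chromocenters(ph0$stack)), 0)
  st_nosat <- image_stack(list(dapi = array(0, c(5, 5, 5))),
                          c(x = 0.1, y = 0.1, z = 0.1))
  expect_error(detect_ec_fragments(st_nosat, regs), "satellite")
})

test_that("prevalence reports the positive count pair", {
  p <- ec_prevalence(c(1, 2, 0, 1, 1, 3, 1, 1))
  expect_equal(p$n_positive, 7)
  expect_equal(p$n_total, 8)
  expect_equal(p$prevalence_pct, 87.5)
  expect_error(ec_prevalence(integer(0)), "no nuclei")
})

test_that("cohort summaries handle degenerate groups", {
  mk_morph <- function(vols) nucleus_morphometry(
    lapply(seq_along(vols), function(i)
      structure(list(id = i, volume = vols[i], sphericity = 0.9),
                class = "chromocenter_region")))
  m1 <- mk_morph(c(5, 7)); m2 <- mk_morph(c(5, 7)); m3 <- mk_morph(c(4))
  s <- summarize_cohort(list(m1, m2, m3), c("a", "a", "b"))
  a <- s$summary[s$summary$group == "a", ]
  expect_equal(a$mean_count, 2)
  expect_equal(a$sd_count, 0)           # identical duplicated nuclei
  b <- s$summary[s$summary$group == "b", ]
  expect_true(b$sd_undefined)
  expect_true(is.na(b$sd_count))
  expect_equal(unname(s$five_number$a$volume_um3["median"]), 6)
  expect_error(summarize_cohort(list(m1), c("a", "b")), "one label")
})

test_that("projection mode reports areas, never volumes", {
  cfg <- fast_phantom_config(poisson_scale = 0, gaussian_sd = 0, seed = 9)
  ph <- gen_nucleus_phantom(cfg)
  mip <- max_intensity_projection(ph$stack)
  expect_equal(dim(mip), dim(ph$stack$channels$dapi)[1:2])
  proj <- segment_projection(ph$stack)
  expect_true(all(c("id", "area_um2") %in% names(proj)))
  expect_gte(nrow(proj), 1)
  # projection merges objects that overlap in z-projection, so the count
  # is at most the planted count
  expect_lte(nrow(proj), ph$ground_truth$n_chromocenters)
})
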
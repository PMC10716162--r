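# Shared fixture builders. All geometry is generated in code at test time;
# nothing is read from disk.

# digital ellipsoid mask with semi-axes (a, b, c) um along (x, y, z)
make_ellipsoid_mask <- function(a, b, c, vs, pad = 6) {
  ny <- ceiling(2 * (b + pad * vs[["y"]]) / vs[["y"]])
  nx <- ceiling(2 * (a + pad * vs[["x"]]) / vs[["x"]])
  nz <- ceiling(2 * (c + pad * vs[["z"]]) / vs[["z"]])
  cy <- ny / 2 * vs[["y"]]; cx <- nx / 2 * vs[["x"]]; cz <- nz / 2 * vs[["z"]]
  y <- (seq_len(ny) - 0.5) * vs[["y"]]
  x <- (seq_len(nx) - 0.5) * vs[["x"]]
  z <- (seq_len(nz) - 0.5) * vs[["z"]]
  arr <- array(FALSE, c(ny, nx, nz))
  sl <- outer(((y - cy) / b)^2, ((x - cx) / a)^2, "+")
  for (k in seq_len(nz)) arr[, , k] <- sl + ((z[k] - cz) / c)^2 <= 1
  arr
}

# small, fast phantom config (single-figure-second rendering)
fast_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(nucleus_radius = 6, nucleolus_radius = 1.8,
         configuration = "NSN",
         n_chromocenters_mean = 4, n_chromocenters_sd = 0,
         volume_mean = 6, volume_sd = 2,
         voxel_size = c(x = 0.2, y = 0.2, z = 0.4),
         psf_sigma = 0.15, poisson_scale = 25, gaussian_sd = 120,
         seed = 1),
    list(...))
  do.call(nucleus_phantom_config, args)
}

# small transcriptome cohort for fast clock tests
fast_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400, n_samples = 120, frac_age_responsive = 0.1,
         n_signal_processes = 6, seed = 1),
    list(...))
  do.call(transcriptome_config, args)
}

fast_clock_hp <- list(n_trees = 150, max_depth = 3,
                      learning_rate = 0.08, subsample = 0.8)

prolate_spheroid_area <- function(a, b) {
  # surface area of a prolate spheroid with semi-axes (a, b, b), a > b
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}
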
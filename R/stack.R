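#' Multi-channel 3D image stack
#'
#' Container for a fluorescence image stack: one or more named channels
#' (typically `dapi`, `satellite`, `h2b`), each a 3D array with dimensions
#' ordered (y, x, z), plus the physical voxel size in micrometres.
#'
#' Physical coordinates follow the voxel-centre convention: the centre of
#' voxel `(i, j, k)` (1-based R indices) sits at
#' `((i - 0.5) * vs["y"], (j - 0.5) * vs["x"], (k - 0.5) * vs["z"])` µm.
#'
#' @param channels named list of 3D numeric arrays, identical dimensions.
#' @param voxel_size named numeric vector `c(x=, y=, z=)` in µm, all > 0.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of 3D arrays")
  nms <- names(channels)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions")
  if (any(dims[[1]] < 1L)) stop("all dimensions must be >= 1")
  voxel_size <- normalize_voxel_size(voxel_size)
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

normalize_voxel_size <- function(vs) {
  if (is.null(vs)) stop("voxel size is required and has no default")
  if (is.null(names(vs)) || !all(c("x", "y", "z") %in% names(vs))) {
    if (length(vs) != 3L) stop("voxel_size must have components x, y, z")
    names(vs) <- c("x", "y", "z")
  }
  vs <- vs[c("x", "y", "z")]
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop("voxel_size components must be finite and > 0")
  vs
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d x %d voxels (y, x, z), channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("voxel size: %.4g x %.4g x %.4g um (x, y, z)\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$channels[[1]])

#' Voxel volume of a stack in cubic micrometres
#' @param stack an `image_stack` (or a named voxel-size vector).
#' @return scalar volume of one voxel, µm³.
#' @export
voxel_volume <- function(stack) {
  vs <- if (inherits(stack, "image_stack")) stack$voxel_size
        else normalize_voxel_size(stack)
  unname(prod(vs))
}

get_channel <- function(stack, channel) {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack")
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[channel]]
}

# physical (y, x, z) coordinates in um for linear voxel indices
voxel_coords_um <- function(idx, dims, voxel_size) {
  ny <- dims[1]; nx <- dims[2]
  i <- ((idx - 1L) %% ny) + 1L
  j <- (((idx - 1L) %/% ny) %% nx) + 1L
  k <- ((idx - 1L) %/% (ny * nx)) + 1L
  cbind(y = (i - 0.5) * voxel_size["y"],
        x = (j - 0.5) * voxel_size["x"],
        z = (k - 0.5) * voxel_size["z"])
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 16-bit unsigned integers (values are rounded
#' and clipped to \[0, 65535\]), pages ordered channel-major (all z of
#' channel 1, then channel 2, ...). The sidecar `<path>.json` records the
#' voxel size, channel names, dimensions and, optionally, ground truth, so
#' the stack round-trips without loss of metadata.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @param ground_truth optional list, serialized into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, ground_truth = NULL) {
  d <- stack_dim(stack)
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- pmin(pmax(round(stack$channels[[ch]]), 0), 65535)
    for (k in seq_len(d[3])) pages[[length(pages) + 1L]] <- a[, , k] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    voxel_size_um = as.list(stack$voxel_size),
    channels = names(stack$channels),
    dim_yxz = d,
    ground_truth = ground_truth
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack from TIFF (+ optional JSON sidecar)
#'
#' Voxel size is resolved with priority: the `voxel_size` argument, then the
#' sidecar `<path>.json`, then TIFF resolution tags (x/y only; plain TIFF
#' carries no z spacing). If no source provides a complete voxel size the
#' read fails -- there is deliberately no silent default, because every
#' micrometre-valued measurement depends on it.
#'
#' @param path TIFF file written by [write_stack()] or compatible.
#' @param voxel_size optional named `c(x=, y=, z=)` µm override.
#' @param channels optional character vector of channel names override.
#' @return an `image_stack`; ground truth from the sidecar, if present, is
#'   attached as attribute `"ground_truth"`.
#' @export
read_stack <- function(path, voxel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL

  vs <- voxel_size
  if (is.null(vs) && !is.null(sidecar$voxel_size_um))
    vs <- unlist(sidecar$voxel_size_um)
  if (is.null(vs)) {
    info <- attributes(pages[[1]])
    if (!is.null(info$x.resolution) && !is.null(info$resolution.unit)) {
      # resolution tags give pixels per unit; no z spacing in plain TIFF
      stop("TIFF resolution tags do not carry z spacing; ",
           "supply `voxel_size` or a sidecar")
    }
    stop("voxel size not available from arguments, sidecar or metadata")
  }
  vs <- normalize_voxel_size(vs)

  chn <- channels
  if (is.null(chn)) chn <- sidecar$channels
  if (is.null(chn)) chn <- "dapi"
  n_pages <- length(pages)
  if (n_pages %% length(chn) != 0L)
    stop(sprintf("%d TIFF pages not divisible by %d channels",
                 n_pages, length(chn)))
  nz <- n_pages %/% length(chn)
  d2 <- dim(pages[[1]])
  out <- list()
  p <- 1L
  for (ch in chn) {
    a <- array(0, dim = c(d2[1], d2[2], nz))
    for (k in seq_len(nz)) {
      a[, , k] <- round(pages[[p]] * 65535)
      p <- p + 1L
    }
    out[[ch]] <- a
  }
  st <- image_stack(out, vs)
  if (!is.null(sidecar$ground_truth))
    attr(st, "ground_truth") <- sidecar$ground_truth
  st
}
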
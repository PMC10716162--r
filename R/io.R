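#' Read gene sets from a GMT file
#'
#' @param path GMT file (one line per set: name, description, gene ids).
#' @return named list: set name -> character vector of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list: set name -> character vector of gene ids.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to
#'   the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a genes x samples count matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a count matrix as MatrixMarket MTX with index files
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.txt`, `<prefix>.samples.txt`.
#'
#' @param counts genes x samples matrix.
#' @param prefix path prefix.
#' @return `prefix` (write) or the dense matrix (read).
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".genes.txt"))
  writeLines(colnames(counts), paste0(prefix, ".samples.txt"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".samples.txt"))
  m
}

#' Write / read sample metadata (sample_id, age_days, perturbed, group)
#'
#' @param ages named age vector, days.
#' @param perturbed named logical vector.
#' @param path TSV path.
#' @param group optional group labels.
#' @return `path` (write) or a data.frame (read).
#' @export
write_sample_meta <- function(ages, perturbed, path, group = NULL) {
  df <- data.frame(sample_id = names(ages), age_days = as.numeric(ages),
                   perturbed = as.logical(perturbed))
  if (!is.null(group)) df$group <- group
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) read.delim(path)

#' Write / read a track table as CSV
#'
#' Columns: track_id, frame, t_seconds, x_um, y_um, z_um, group (and
#' nucleus_id when present). Micrometre coordinates are written with 4
#' decimal places.
#'
#' @param tracks track data.frame.
#' @param path CSV path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- tracks
  for (col in c("x_um", "y_um", "z_um"))
    if (col %in% names(out)) out[[col]] <- sprintf("%.4f", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) read.csv(path)

#' Serialize a group-comparison or summary result to JSON
#'
#' @param x a result object (list/data.frame).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "group_comparison")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
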
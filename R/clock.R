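#' Normalize a count matrix to log2 counts-per-million
#'
#' Per-sample counts-per-million followed by `log2(x + 1)`. Scale-invariant
#' per sample (doubling one sample's counts leaves its normalized values
#' unchanged) and monotone in raw counts within a sample.
#'
#' @param counts genes x samples non-negative matrix with dimnames.
#' @return normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0]
    stop("zero library size in sample(s): ",
         paste(if (is.null(bad)) which(libsize == 0) else bad,
               collapse = ", "))
  }
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
}

default_clock_hyperparams <- function() {
  list(n_trees = 300, max_depth = 3, learning_rate = 0.05, subsample = 0.8)
}

#' Fit the oocyte RNA age clock (gradient-boosted trees)
#'
#' Boosted regression trees predicting age (days) from normalized
#' expression. Samples flagged as perturbed are trained against
#' `senescence_equivalent_age` (default: the 90th percentile of training
#' ages) instead of their chronological age, so the model learns to map
#' the irradiation-induced transcriptomic shift onto advanced biological
#' age. Per-gene variable importance is total split gain, normalized to
#' sum to 1 over the training gene set.
#'
#' @param X genes x samples normalized matrix (from [normalize_counts()]).
#' @param ages per-sample chronological age, days, > 0.
#' @param perturbed optional logical per-sample flag.
#' @param hyperparams list with `n_trees`, `max_depth`, `learning_rate`,
#'   `subsample`.
#' @param senescence_equivalent_age training target for perturbed samples.
#' @param seed RNG seed; fits are deterministic given the seed
#'   (single-threaded).
#' @return object of class `age_clock`.
#' @export
fit_age_clock <- function(X, ages, perturbed = NULL,
                          hyperparams = default_clock_hyperparams(),
                          senescence_equivalent_age = NULL,
                          seed = 1) {
  if (ncol(X) < 20) stop("need at least 20 training samples")
  if (length(ages) != ncol(X)) stop("one age per sample required")
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("ages must be finite and > 0")
  if (is.null(perturbed)) perturbed <- rep(FALSE, ncol(X))
  rv <- apply(X, 1, var)
  if (all(rv == 0)) stop("all features are constant")
  if (is.null(senescence_equivalent_age))
    senescence_equivalent_age <- unname(quantile(ages, 0.9))
  target <- ifelse(perturbed, senescence_equivalent_age, ages)

  hp <- utils::modifyList(default_clock_hyperparams(), hyperparams)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(t(X), label = target)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = hp$max_depth, eta = hp$learning_rate,
                  subsample = hp$subsample, nthread = 1, seed = seed),
    data = dtrain, nrounds = hp$n_trees, verbose = 0)
  imp_tab <- xgboost::xgb.importance(model = booster)
  importance <- setNames(numeric(nrow(X)), rownames(X))
  if (nrow(imp_tab) > 0)
    importance[imp_tab$Feature] <- imp_tab$Gain
  if (sum(importance) == 0) {
    # a constant target needs no splits; importance is then uninformative
    importance[] <- 1 / length(importance)
  }
  importance <- importance / sum(importance)

  structure(list(booster = booster,
                 genes = rownames(X),
                 importance = importance,
                 hyperparams = hp,
                 senescence_equivalent_age = senescence_equivalent_age,
                 reference_profile = rowMeans(X),
                 training_ages = ages,
                 training_target = target,
                 seed = seed,
                 normalization = "log2(CPM + 1)"),
            class = "age_clock")
}

#' @export
print.age_clock <- function(x, ...) {
  cat(sprintf(
    "age_clock: %d genes, %d trees (depth %d, eta %.3g, subsample %.2g)\n",
    length(x$genes), x$hyperparams$n_trees, x$hyperparams$max_depth,
    x$hyperparams$learning_rate, x$hyperparams$subsample))
  cat(sprintf("trained on %d samples, ages %.0f-%.0f days\n",
              length(x$training_ages), min(x$training_ages),
              max(x$training_ages)))
  invisible(x)
}

#' Predict biological age (days) for expression profiles
#'
#' Genes absent from `X` are imputed at the model's training-mean value
#' (with a warning), which makes their contribution neutral; profiles with
#' no overlapping genes are an error.
#'
#' @param model an `age_clock`.
#' @param X genes x samples normalized matrix (or a named vector for one
#'   sample).
#' @return named numeric vector of predicted ages, days.
#' @export
predict_age <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(names(X), "sample"))
  common <- intersect(model$genes, rownames(X))
  if (length(common) == 0) stop("no genes in common with the model")
  missing <- setdiff(model$genes, rownames(X))
  M <- matrix(rep(model$reference_profile, ncol(X)),
              nrow = length(model$genes),
              dimnames = list(model$genes, colnames(X)))
  M[common, ] <- X[common, ]
  if (length(missing) > 0)
    warning(sprintf("%d model genes missing; imputed at training mean",
                    length(missing)))
  preds <- predict(model$booster, xgboost::xgb.DMatrix(t(M)))
  setNames(as.numeric(preds), colnames(M))
}

#' K-fold cross-validated clock performance (MAE in days)
#'
#' Folds are stratified by age quantile: samples are ranked by (effective)
#' target age and assigned to folds cyclically within the ranking, so each
#' fold spans the age range. Each fold's model is fit on the remaining
#' folds and scored by mean absolute error on the held-out fold.
#'
#' @inheritParams fit_age_clock
#' @param k number of folds, >= 2 and <= number of samples.
#' @return list with `fold_mae`, `mae` (mean over folds), `predictions`
#'   and `fold` assignment.
#' @export
cross_validate_clock <- function(X, ages, perturbed = NULL, k = 5,
                                 hyperparams = default_clock_hyperparams(),
                                 senescence_equivalent_age = NULL,
                                 seed = 1) {
  n <- ncol(X)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  if (is.null(perturbed)) perturbed <- rep(FALSE, n)
  if (is.null(senescence_equivalent_age))
    senescence_equivalent_age <- unname(quantile(ages, 0.9))
  target <- ifelse(perturbed, senescence_equivalent_age, ages)

  set.seed(seed)
  ord <- order(target, runif(n))  # random tie-break, then age-ranked
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)

  preds <- numeric(n)
  fold_mae <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_age_clock(X[, tr, drop = FALSE], ages[tr],
                           perturbed = perturbed[tr],
                           hyperparams = hyperparams,
                           senescence_equivalent_age =
                             senescence_equivalent_age,
                           seed = seed + f)
    p <- predict_age(model, X[, !tr, drop = FALSE])
    preds[!tr] <- p
    fold_mae[f] <- mean(abs(p - target[!tr]))
  }
  list(fold_mae = fold_mae, mae = mean(fold_mae),
       predictions = setNames(preds, colnames(X)), fold = fold)
}

#' Baseline (young-control) expression profile
#'
#' @param X genes x samples normalized matrix.
#' @param samples column names or indices of the designated young-control
#'   samples.
#' @return named per-gene mean vector of class `baseline_profile`.
#' @export
baseline_profile <- function(X, samples) {
  sel <- X[, samples, drop = FALSE]
  if (ncol(sel) == 0) stop("no baseline samples selected")
  structure(rowMeans(sel), class = "baseline_profile")
}

#' Per-gene impact of a profile's deviation from baseline
#'
#' `impact_g = I_g * |x_g - baseline_g|`: the model's variable importance
#' for the gene times the absolute difference of its normalized value from
#' the young-control baseline. Non-negative; zero when the profile equals
#' the baseline; linear in |D|.
#'
#' @param model an `age_clock` (source of importance I).
#' @param profile named per-gene normalized expression vector.
#' @param baseline a [baseline_profile()] (gene set must match the
#'   model's).
#' @return named per-gene impact vector over the model gene set.
#' @export
gene_impact <- function(model, profile, baseline) {
  genes <- model$genes
  if (!all(genes %in% names(baseline)))
    stop("baseline does not cover the model gene set")
  if (!all(genes %in% names(profile)))
    stop("profile does not cover the model gene set")
  D <- profile[genes] - unclass(baseline)[genes]
  imp <- model$importance[genes] * abs(D)
  setNames(as.numeric(imp), genes)
}

#' Aggregate gene impacts into process impacts, min-max normalized
#'
#' Process impact is the sum of member-gene impacts. Per contrast (one
#' column of the heatmap), values are min-max normalized across processes
#' to \[0, 1\]; an all-zero vector maps to all zeros, and a degenerate
#' constant non-zero vector maps to all ones. Genes without annotation are
#' ignored (their count is reported as attribute `"n_unannotated"`).
#'
#' @param impacts named gene-impact vector (or genes x contrasts matrix).
#' @param annotation named list: process -> character vector of gene ids.
#' @param normalize min-max normalize across processes (default TRUE).
#' @return data.frame with process, raw impact and normalized impact (one
#'   pair of columns per contrast).
#' @export
process_impact <- function(impacts, annotation, normalize = TRUE) {
  if (length(annotation) == 0) stop("empty annotation")
  if (is.null(dim(impacts)))
    impacts <- matrix(impacts, ncol = 1,
                      dimnames = list(names(impacts), "impact"))
  annotated <- unique(unlist(annotation))
  n_unannotated <- sum(!rownames(impacts) %in% annotated)
  raw <- vapply(annotation, function(gs) {
    gs <- intersect(gs, rownames(impacts))
    if (length(gs) == 0) rep(0, ncol(impacts))
    else colSums(impacts[gs, , drop = FALSE])
  }, numeric(ncol(impacts)))
  raw <- matrix(raw, nrow = ncol(impacts),
                dimnames = list(colnames(impacts), names(annotation)))
  raw <- t(raw)  # processes x contrasts
  out <- data.frame(process = rownames(raw), raw, check.names = FALSE)
  names(out)[-1] <- paste0("raw_", colnames(raw))
  if (normalize) {
    norm <- apply(raw, 2, function(v) {
      rng <- range(v)
      if (rng[2] == rng[1]) {
        if (rng[2] == 0) rep(0, length(v)) else rep(1, length(v))
      } else (v - rng[1]) / (rng[2] - rng[1])
    })
    norm <- matrix(norm, nrow = nrow(raw), dimnames = dimnames(raw))
    for (j in colnames(norm)) out[[paste0("normalized_", j)]] <- norm[, j]
  }
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Export a process-impact heatmap
#'
#' Writes the normalized process x contrast matrix as CSV and, when the
#' pheatmap package is available, renders a PDF heatmap.
#'
#' @param impact_table result of [process_impact()].
#' @param path_prefix output path prefix (writes `<prefix>.csv` and
#'   optionally `<prefix>.pdf`).
#' @return the normalized matrix, invisibly.
#' @export
export_impact_heatmap <- function(impact_table, path_prefix) {
  cols <- grep("^normalized_", names(impact_table), value = TRUE)
  if (length(cols) == 0) stop("impact table has no normalized columns")
  m <- as.matrix(impact_table[, cols, drop = FALSE])
  rownames(m) <- impact_table$process
  colnames(m) <- sub("^normalized_", "", cols)
  write.csv(data.frame(process = rownames(m), m, check.names = FALSE),
            paste0(path_prefix, ".csv"), row.names = FALSE)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::pdf(paste0(path_prefix, ".pdf"), width = 6,
                   height = 0.25 * nrow(m) + 2)
    pheatmap::pheatmap(m, cluster_cols = FALSE,
                       main = "process impact (0-1 normalized)")
    grDevices::dev.off()
  }
  invisible(m)
}
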
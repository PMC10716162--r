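#' Configuration for a synthetic age-structured transcriptome cohort
#'
#' Emulates the structure of an oocyte aging-cohort count matrix: a
#' fraction of genes carries a monotone log-linear expression trend in
#' chronological age; counts are drawn with negative-binomial
#' overdispersion around sample-specific size factors. "Irradiated"
#' samples are additionally shifted along the aging program: every
#' age-responsive gene moves as if the sample were `irradiation_shift`
#' days older (the shift is expressed in multiples of `slope_scale`).
#' Every gene is annotated to exactly one of `n_processes` toy ontology
#' processes; age-responsive genes are concentrated in a subset of
#' processes so that process-level attribution has a planted signal.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param age_range days, `c(min, max)`.
#' @param frac_age_responsive fraction of genes with a planted age trend
#'   (strictly between 0 and 1; must give at least one gene).
#' @param slope_scale log2-expression units per day for responsive genes.
#' @param dispersion negative-binomial overdispersion (rnbinom `size` is
#'   `1/dispersion`).
#' @param irradiation_shift days-equivalent shift applied to responsive
#'   genes of perturbed samples.
#' @param frac_perturbed fraction of samples flagged as perturbed.
#' @param n_processes number of ontology processes, default 29.
#' @param n_signal_processes responsive genes are assigned among the first
#'   this-many processes.
#' @param seed integer RNG seed.
#' @return object of class `transcriptome_config`.
#' @export
transcriptome_config <- function(n_genes = 1000,
                                 n_samples = 200,
                                 age_range = c(20, 430),
                                 frac_age_responsive = 0.1,
                                 slope_scale = 0.005,
                                 dispersion = 0.1,
                                 irradiation_shift = 300,
                                 frac_perturbed = 0.1,
                                 n_processes = 29,
                                 n_signal_processes = 8,
                                 seed = 1) {
  stopifnot(n_genes >= 10, n_samples >= 4, length(age_range) == 2,
            age_range[1] > 0, age_range[2] > age_range[1],
            frac_age_responsive > 0, frac_age_responsive < 1,
            slope_scale > 0, dispersion >= 0,
            frac_perturbed >= 0, frac_perturbed < 1,
            n_processes >= 1, n_signal_processes >= 1,
            n_signal_processes <= n_processes)
  if (round(frac_age_responsive * n_genes) < 1)
    stop("frac_age_responsive * n_genes must be at least 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 age_range = age_range,
                 frac_age_responsive = frac_age_responsive,
                 slope_scale = slope_scale,
                 dispersion = dispersion,
                 irradiation_shift = irradiation_shift,
                 frac_perturbed = frac_perturbed,
                 n_processes = as.integer(n_processes),
                 n_signal_processes = as.integer(n_signal_processes),
                 seed = as.integer(seed)),
            class = "transcriptome_config")
}

# toy top-level process names, loosely modelled on a cell-biology ontology
process_names <- function(n) {
  base <- c("cell_communication", "posttranslational_modification",
            "chromatin_dynamics", "histone_dynamics",
            "intracellular_degradation", "vesicle_traffic",
            "cytoskeleton_dynamics", "dna_recombination_repair",
            "gene_expression", "cell_cycle", "cell_division",
            "rna_processing", "translation", "protein_folding",
            "metabolism_carbohydrate", "metabolism_lipid",
            "metabolism_nucleotide", "mitochondrial_function",
            "ion_transport", "membrane_organization", "nuclear_transport",
            "signal_transduction", "apoptosis", "autophagy",
            "dna_replication", "telomere_maintenance", "ribosome_biogenesis",
            "stress_response", "extracellular_matrix")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("process_%02d", seq_len(n - length(base))))
}

#' Generate a synthetic transcriptome cohort with known ground truth
#'
#' @param config a [transcriptome_config()].
#' @return list with `counts` (genes x samples integer matrix), `ages`
#'   (days), `perturbed` (logical), `annotation` (named list process ->
#'   gene ids), and `ground_truth` (planted slopes, responsive gene ids,
#'   signal processes).
#' @export
gen_transcriptome_cohort <- function(config) {
  stopifnot(inherits(config, "transcriptome_config"))
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  genes <- sprintf("gene%04d", seq_len(ng))
  samples <- sprintf("S%03d", seq_len(ns))
  ages <- runif(ns, config$age_range[1], config$age_range[2])
  # irradiation-like perturbation is applied to young samples (below the
  # cohort median age), mirroring study designs that irradiate young
  # oocytes and compare against aged unperturbed ones
  perturbed <- rep(FALSE, ns)
  n_pert <- round(config$frac_perturbed * ns)
  if (n_pert > 0) {
    young <- which(ages <= median(ages))
    perturbed[sample(young, min(n_pert, length(young)))] <- TRUE
  }

  n_resp <- round(config$frac_age_responsive * ng)
  responsive <- sort(sample(ng, n_resp))
  slopes <- numeric(ng)
  slopes[responsive] <- config$slope_scale *
    sample(c(-1, 1), n_resp, replace = TRUE)
  base_log2 <- runif(ng, 3, 9)
  age_mid <- mean(config$age_range)

  eff_age <- matrix(rep(ages, each = ng), ng, ns)
  eff_age[responsive, perturbed] <- eff_age[responsive, perturbed] +
    config$irradiation_shift
  mu_log2 <- base_log2 + slopes * (eff_age - age_mid)
  size_factor <- exp(rnorm(ns, 0, 0.25))
  mu <- sweep(2^mu_log2, 2, size_factor, "*")
  counts <- matrix(
    if (config$dispersion > 0)
      rnbinom(ng * ns, mu = as.numeric(mu), size = 1 / config$dispersion)
    else rpois(ng * ns, as.numeric(mu)),
    ng, ns, dimnames = list(genes, samples))

  procs <- process_names(config$n_processes)
  assignment <- character(ng)
  assignment[responsive] <- sample(procs[seq_len(config$n_signal_processes)],
                                   n_resp, replace = TRUE)
  assignment[-responsive] <- sample(procs, ng - n_resp, replace = TRUE)
  annotation <- split(genes, factor(assignment, levels = procs))
  annotation <- annotation[vapply(annotation, length, 1L) > 0]

  list(counts = counts,
       ages = setNames(ages, samples),
       perturbed = setNames(perturbed, samples),
       annotation = annotation,
       ground_truth = list(
         responsive_genes = genes[responsive],
         slopes_log2_per_day = setNames(slopes, genes),
         signal_processes = procs[seq_len(config$n_signal_processes)],
         irradiation_shift = config$irradiation_shift,
         seed = config$seed))
}
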
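test_that("normalization is CPM log2 with the documented properties", {
  counts <- matrix(c(10, 0, 990e3 + 9990, 20, 5, 2e6 - 25), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  X <- normalize_counts(counts)
  # a sample with library size exactly 1e6 has CPM equal to raw counts
  lib1 <- unname(colSums(counts)[1])
  expect_equal(lib1, 1e6)
  expect_equal(X["g1", "s1"], log2(10 + 1))
  expect_equal(X["g2", "s1"], 0)          # zero count -> normalized 0
  # doubling all counts of one sample leaves it unchanged
  c2 <- counts; c2[, 2] <- c2[, 2] * 2
  expect_equal(normalize_counts(c2)[, 2], X[, 2])
  bad <- counts; bad[, 2] <- 0
  expect_error(normalize_counts(bad), "s2")
})

test_that("clock fits are seed-deterministic and handle degenerate ages", {
  coh <- gen_transcriptome_cohort(fast_cohort_config(seed = 4))
  X <- normalize_counts(coh$counts)
  m1 <- fit_age_clock(X, coh$ages, coh$perturbed, hyperparams = fast_clock_hp,
                      seed = 3)
  m2 <- fit_age_clock(X, coh$ages, coh$perturbed, hyperparams = fast_clock_hp,
                      seed = 3)
  expect_identical(predict_age(m1, X), predict_age(m2, X))
  expect_equal(sum(m1$importance), 1, tolerance = 1e-9)
  expect_true(all(m1$importance >= 0))
  # constant ages, zero noise: predictions collapse to the constant
  Xc <- X[, 1:30]
  mc <- fit_age_clock(Xc, rep(100, 30), hyperparams = fast_clock_hp,
                      seed = 1)
  expect_equal(unname(predict_age(mc, Xc)), rep(100, 30), tolerance = 0.5)
  expect_error(fit_age_clock(X[, 1:10], coh$ages[1:10]), "20")
  expect_error(fit_age_clock(matrix(1, 5, 30,
                                    dimnames = list(paste0("g", 1:5),
                                                    paste0("s", 1:30))),
                             rep(50, 30)), "constant")
})

test_that("training recovers ages on a clock_default-style cohort", {
  coh <- gen_transcriptome_cohort(fast_cohort_config(n_samples = 200,
                                                     seed = 8))
  X <- normalize_counts(coh$counts)
  m <- fit_age_clock(X, coh$ages, coh$perturbed, hyperparams = fast_clock_hp,
                     seed = 2)
  pred <- predict_age(m, X)
  keep <- !coh$perturbed
  expect_lt(mean(abs(pred[keep] - coh$ages[keep])), 15)
})

test_that("cross-validation behaves across signal regimes", {
  # degenerate single-gene linear signal: near-zero CV error
  n <- 60
  ages <- seq(20, 430, length.out = n)
  X <- rbind(gene_a = ages / 100, gene_b = rep(1, n),
             gene_c = sin(seq_len(n)))
  colnames(X) <- paste0("s", seq_len(n))
  cv <- cross_validate_clock(X, ages, k = 5, hyperparams = fast_clock_hp,
                             seed = 1)
  expect_lt(cv$mae, 0.05 * diff(range(ages)))
  expect_length(cv$fold_mae, 5)
  # fold assignment errors
  expect_error(cross_validate_clock(X, ages, k = 1), "k must be")
  expect_error(cross_validate_clock(X, ages, k = 100), "exceeds")
  # CV MAE invariant to sample ordering given the seed
  ord <- sample(n)
  cv2 <- cross_validate_clock(X[, ord], ages[ord], k = 5,
                              hyperparams = fast_clock_hp, seed = 1)
  expect_equal(cv2$mae, cv$mae, tolerance = 0.15)
})

test_that("perturbed samples are predicted older than matched controls", {
  coh <- gen_transcriptome_cohort(fast_cohort_config(n_samples = 160,
                                                     frac_perturbed = 0.15,
                                                     seed = 6))
  X <- normalize_counts(coh$counts)
  m <- fit_age_clock(X, coh$ages, coh$perturbed, hyperparams = fast_clock_hp,
                     seed = 2)
  pred <- predict_age(m, X)
  frac_older <- mean(vapply(which(coh$perturbed), function(i) {
    ctrl <- which(!coh$perturbed & abs(coh$ages - coh$ages[i]) < 40)
    pred[i] > mean(pred[ctrl])
  }, TRUE))
  expect_gte(frac_older, 0.95)
})

test_that("increasing the irradiation shift never lowers perturbed ages", {
  med_pred <- vapply(c(0, 150, 300), function(shift) {
    med <- numeric(3)
    for (s in 1:3) {
      coh <- gen_transcriptome_cohort(fast_cohort_config(
        n_samples = 100, irradiation_shift = shift, frac_perturbed = 0.2,
        seed = s))
      X <- normalize_counts(coh$counts)
      m <- fit_age_clock(X, coh$ages, coh$perturbed,
                         hyperparams = fast_clock_hp, seed = 1)
      med[s] <- median(predict_age(m, X)[coh$perturbed])
    }
    mean(med)
  }, 0)
  expect_true(all(diff(med_pred) > -5))
})

test_that("gene impact is exactly I * |D|", {
  coh <- gen_transcriptome_cohort(fast_cohort_config(n_genes = 50,
                                                     n_samples = 40,
                                                     seed = 5))
  X <- normalize_counts(coh$counts)
  m <- fit_age_clock(X, coh$ages, hyperparams = fast_clock_hp, seed = 1)
  bl <- baseline_profile(X, 1:5)
  # profile equal to baseline: all impacts zero
  expect_true(all(gene_impact(m, unclass(bl), bl) == 0))
  # hand example: I = (.5, .3, .2), D = (2, -1, 0) -> (1.0, 0.3, 0.0)
  mock <- m
  mock$genes <- c("a", "b", "c")
  mock$importance <- c(a = 0.5, b = 0.3, c = 0.2)
  blv <- structure(c(a = 1, b = 1, c = 1), class = "baseline_profile")
  gi <- gene_impact(mock, c(a = 3, b = 0, c = 1), blv)
  expect_equal(unname(gi), c(1.0, 0.3, 0.0))
  # linearity: doubling |D| doubles every impact
  gi2 <- gene_impact(mock, c(a = 5, b = -1, c = 1), blv)
  expect_equal(unname(gi2), 2 * unname(gi))
  # brute-force oracle on random vectors
  set.seed(9)
  for (rep in 1:25) {
    prof <- setNames(rnorm(length(m$genes)), m$genes)
    base <- structure(setNames(rnorm(length(m$genes)), m$genes),
                      class = "baseline_profile")
    got <- gene_impact(m, prof, base)
    want <- vapply(m$genes, function(g)
      m$importance[[g]] * abs(prof[[g]] - unclass(base)[[g]]), 0)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("process impact aggregates and min-max normalizes", {
  ann <- list(A = c("g1", "g2"), B = "g3")
  imp <- c(g1 = 1.0, g2 = 0.3, g3 = 0.0)
  tab <- process_impact(imp, ann)
  expect_equal(tab$raw_impact, c(1.3, 0))
  expect_equal(tab$normalized_impact, c(1, 0))
  # permuting gene order changes nothing
  tab2 <- process_impact(imp[c(3, 1, 2)], ann)
  expect_equal(tab2$raw_impact, tab$raw_impact)
  # single process: 1 unless raw is 0
  expect_equal(process_impact(imp, list(A = names(imp)))$normalized_impact,
               1)
  expect_equal(process_impact(imp * 0,
                              list(A = names(imp)))$normalized_impact, 0)
  expect_error(process_impact(imp, list()), "empty annotation")
  # unannotated genes are ignored with a count
  tab3 <- process_impact(imp, list(A = "g1"))
  expect_equal(attr(tab3, "n_unannotated"), 2)
})

test_that("prediction imputes missing genes at the training mean", {
  coh <- gen_transcriptome_cohort(fast_cohort_config(n_genes = 60,
                                                     n_samples = 40,
                                                     seed = 7))
  X <- normalize_counts(coh$counts)
  m <- fit_age_clock(X, coh$ages, hyperparams = fast_clock_hp, seed = 1)
  full <- predict_age(m, X[, 1, drop = FALSE])
  expect_warning(part <- predict_age(m, X[1:50, 1, drop = FALSE]),
                 "imputed")
  expect_true(is.finite(part))
  expect_error(predict_age(m, matrix(1, 2, 1,
                                     dimnames = list(c("zz1", "zz2"),
                                                     "s"))),
               "no genes in common")
  # identical duplicated sample gives the identical prediction
  X2 <- cbind(X[, 1, drop = FALSE], X[, 1, drop = FALSE])
  colnames(X2) <- c("a", "b")
  p <- predict_age(m, X2)
  expect_equal(unname(p[1]), unname(p[2]))
  expect_equal(unname(p[1]), unname(full[1]))
})
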
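#' Cohen's d effect size (pooled-SD form)
#'
#' `d = (mean(a) - mean(b)) / s_p` with
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' Antisymmetric under group swap. A zero pooled SD yields `NA` with a
#' warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized skewness and kurtosis statistics into
#' `K2 = Z1^2 + Z2^2`, compared against chi-squared with 2 df. Requires
#' n >= 8 (the kurtosis transform is undefined below that).
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2) and `p_value`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("constant sample")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness -> Z1 (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis -> Z2 (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Two-sample comparison (t-test or Mann-Whitney, auto-selectable)
#'
#' Two-sided unpaired comparison. With `method = "auto"` the parametric
#' t-test is used unless the D'Agostino-Pearson normality test rejects at
#' p < 0.05 in either group (mirroring test selection "according to the
#' sample distribution"); groups too small for the normality test (n < 8)
#' default to the t-test with a note.
#'
#' @param a,b numeric vectors, n >= 3 each.
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param conf_level confidence level for the interval.
#' @return list of class `group_comparison`: test, statistic, p_value,
#'   cohens_d, conf_int, n, plus `flag` for degenerate cases.
#' @export
compare_two <- function(a, b, method = c("auto", "t", "mann_whitney"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  flag <- NULL
  if (method == "auto") {
    if (length(a) >= 8 && length(b) >= 8 &&
        var(a) > 0 && var(b) > 0) {
      pa <- dagostino_pearson(a)$p_value
      pb <- dagostino_pearson(b)$p_value
      method <- if (min(pa, pb) < 0.05) "mann_whitney" else "t"
    } else {
      method <- "t"
      flag <- "groups too small or constant for normality pre-check"
    }
  }
  d <- tryCatch(cohens_d(a, b), warning = function(w) NA_real_)
  if (method == "t") {
    if (var(c(a, b)) == 0) {
      res <- list(test = "t", statistic = 0, p_value = 1,
                  conf_int = c(0, 0))
      flag <- "all values identical"
    } else {
      tt <- t.test(a, b, conf.level = conf_level)
      res <- list(test = "t", statistic = unname(tt$statistic),
                  p_value = tt$p.value, conf_int = unname(tt$conf.int))
    }
  } else {
    if (length(unique(c(a, b))) == 1) {
      res <- list(test = "mann_whitney", statistic = NA_real_,
                  p_value = NA_real_, conf_int = c(NA_real_, NA_real_))
      flag <- "ties-only data; rank test degenerate"
    } else {
      wt <- suppressWarnings(
        wilcox.test(a, b, conf.int = TRUE, conf.level = conf_level,
                    exact = FALSE))
      res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value, conf_int = unname(wt$conf.int))
    }
  }
  structure(c(res, list(cohens_d = d, n = c(length(a), length(b)),
                        flag = flag)),
            class = "group_comparison")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor), >= 3 levels, each with
#'   n >= 2.
#' @param conf_level confidence level for the Tukey intervals.
#' @return list of class `group_comparison`: `f_statistic`, `p_value`
#'   (omnibus), and `pairs`, a data.frame with per-pair difference, Tukey
#'   interval, adjusted p, and the unadjusted pooled-variance t-test p.
#' @export
anova_tukey <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  if (nlevels(g) < 3) stop("anova_tukey needs >= 3 groups")
  ns <- table(g)
  if (any(ns < 2)) stop("every group needs n >= 2")
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit, conf.level = conf_level)$g
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  pairs <- data.frame(
    pair = rownames(tuk),
    diff = tuk[, "diff"], lwr = tuk[, "lwr"], upr = tuk[, "upr"],
    p_adj = tuk[, "p adj"], row.names = NULL)
  # unadjusted pooled-variance pairwise p, for adjustment-property checks
  means <- tapply(values, g, mean)
  pairs$p_unadj <- vapply(seq_len(nrow(pairs)), function(i) {
    nm <- strsplit(pairs$pair[i], "-", fixed = TRUE)[[1]]
    se <- sqrt(mse * (1 / ns[nm[1]] + 1 / ns[nm[2]]))
    2 * pt(abs(means[nm[1]] - means[nm[2]]) / se, dfres, lower.tail = FALSE)
  }, 0)
  structure(list(test = "anova_tukey",
                 f_statistic = an["g", "F value"],
                 p_value = an["g", "Pr(>F)"],
                 pairs = pairs,
                 group_means = means,
                 n = as.integer(ns)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$pairs)) {
    cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g\n",
                x$f_statistic, x$p_value))
    print(x$pairs, digits = 4)
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.4g, Cohen's d = %.3g\n",
                x$test, x$statistic, x$p_value, x$cohens_d))
    cat(sprintf("CI [%.4g, %.4g]\n", x$conf_int[1], x$conf_int[2]))
  }
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Five-number summary (box-plot statistics)
#'
#' Minimum, lower quartile, median, upper quartile, maximum; quartiles use
#' the linear-interpolation convention (R quantile type 7), matching
#' common plotting defaults.
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric vector (min, q25, median, q75, max).
#' @export
five_number <- function(values) {
  if (length(values) == 0) stop("empty input")
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  setNames(q, c("min", "q25", "median", "q75", "max"))
}

#' Deterministic sample with exact mean and SD
#'
#' Rescales a fixed spread pattern so the returned vector has exactly the
#' requested sample mean and SD; used to reconstruct groups from published
#' summary statistics.
#'
#' @param n sample size (>= 2).
#' @param mean,sd target sample mean and SD.
#' @return numeric vector of length n.
#' @export
sample_with_moments <- function(n, mean, sd) {
  stopifnot(n >= 2)
  base <- seq(-1, 1, length.out = n)
  base <- (base - mean(base)) / sd(base)
  mean + sd * base
}
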
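# Chromosome-level dosage-compensation inference.

#' Chromosome-wise mean log2 m:f with no-intercept regression
#'
#' Regresses per-gene log2 m:f on chromosome identity without an intercept:
#' each coefficient is then the chromosome's mean log2 m:f, the global F
#' statistic tests the joint null that every chromosome mean is zero (full
#' compensation everywhere), and per-chromosome confidence intervals are
#' Bonferroni-adjusted for the number of chromosomes
#' (level `1 - alpha / n_chrom`). Estimates and intervals are reported on
#' the ratio scale by exponentiation. Fitting per gene is algebraically
#' identical (in point estimates) to regressing per-chromosome means
#' weighted by gene counts; per-gene residual variance is used for
#' inference. Chromosomes with fewer than 2 genes are excluded with a
#' warning.
#'
#' @param mf_table Data frame with columns `chromosome` and `log2_mf` (use
#'   the GC-adjusted table from [remove_gc_effect()] where relevant).
#' @param alpha Family-wise error rate for the Bonferroni intervals.
#' @return Object of class `chrom_mf`: list with `summary` (data frame
#'   `chromosome`, `n_genes`, `mean_log2_mf`, `mf_ratio`, `ci_low`,
#'   `ci_high`, `deviates_from_zero`), `f_statistic`, `df1`, `df2`,
#'   `p_value`, `alpha`, `ci_level`.
#' @export
chromosome_mf_regression <- function(mf_table, alpha = 0.05) {
  stopifnot(all(c("chromosome", "log2_mf") %in% names(mf_table)))
  d <- mf_table[is.finite(mf_table$log2_mf) & !is.na(mf_table$chromosome), ,
                drop = FALSE]
  counts <- table(d$chromosome)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding chromosome(s) with < 2 genes: ",
            paste(small, collapse = ", "))
    d <- d[!d$chromosome %in% small, , drop = FALSE]
    counts <- counts[!names(counts) %in% small]
  }
  if (length(counts) < 2)
    stop("need at least two chromosomes with >= 2 genes each", call. = FALSE)
  d$chromosome <- factor(d$chromosome)
  fit <- stats::lm(log2_mf ~ 0 + chromosome, data = d)
  sm <- summary(fit)
  fs <- sm$fstatistic
  n_chrom <- nlevels(d$chromosome)
  ci_level <- 1 - alpha / n_chrom
  ci <- stats::confint(fit, level = ci_level)
  est <- stats::coef(fit)
  chrom_names <- sub("^chromosome", "", names(est))
  out <- data.frame(
    chromosome = chrom_names,
    n_genes = as.integer(counts[chrom_names]),
    mean_log2_mf = unname(est),
    mf_ratio = unname(2^est),
    ci_low = unname(2^ci[, 1]),
    ci_high = unname(2^ci[, 2]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$deviates_from_zero <- out$ci_low > 1 | out$ci_high < 1
  structure(list(
    summary = out,
    f_statistic = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
    p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    alpha = alpha, ci_level = ci_level
  ), class = "chrom_mf")
}

#' @export
print.chrom_mf <- function(x, ...) {
  cat(sprintf("Chromosome m:f regression (no intercept): F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  cat(sprintf("Bonferroni CI level per chromosome: %.4f\n", x$ci_level))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Bootstrap confidence interval for a mean ratio
#'
#' Nonparametric percentile bootstrap over genes, for either the mean of
#' per-gene ratios (`mode = "mean_of_ratios"`, `x` holds ratios) or the
#' ratio of two means (`mode = "ratio_of_means"`, `x` and `y` hold the
#' paired per-gene numerator and denominator, e.g. per-sex mean expression).
#'
#' @param x Numeric vector (per-gene ratios, or numerator values).
#' @param y Numeric vector of denominators, required for
#'   `mode = "ratio_of_means"`.
#' @param mode Point-estimate definition (see above).
#' @param n_boot Bootstrap replicates (>= 100).
#' @param level Interval level (default 0.95).
#' @param seed Optional seed for reproducible resampling.
#' @return List with `point`, `ci_low`, `ci_high`, `level`, `n_boot`.
#' @export
mean_ratio_ci <- function(x, y = NULL,
                          mode = c("mean_of_ratios", "ratio_of_means"),
                          n_boot = 10000, level = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (n_boot < 100)
    stop("`n_boot` must be at least 100", call. = FALSE)
  if (length(x) < 2)
    stop("need at least 2 values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (mode == "mean_of_ratios") {
    point <- mean(x)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    stats_boot <- rowMeans(matrix(x[idx], nrow = n_boot))
  } else {
    if (is.null(y) || length(y) != n)
      stop("`y` must pair with `x` for ratio_of_means", call. = FALSE)
    point <- mean(x) / mean(y)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    stats_boot <- rowMeans(matrix(x[idx], nrow = n_boot)) /
      rowMeans(matrix(y[idx], nrow = n_boot))
  }
  qs <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  list(point = point, ci_low = qs[1], ci_high = qs[2],
       level = level, n_boot = n_boot)
}

#' Z-to-autosome expression ratio within one sex
#'
#' Ratio of mean Z-linked to mean autosomal expression in the given sex,
#' computed on the log2 scale (difference of mean per-gene log2 expression,
#' exponentiated) with a gene-level bootstrap percentile interval (Z and
#' autosomal genes resampled independently). A ratio below 1 in females but
#' near 1 in males indicates female up-regulation of the single Z rather
#' than male down-regulation. Genes with zero mean expression in the sex are
#' dropped on the log scale.
#'
#' @param expr An [expression_matrix()] (RPKM) with chromosome labels.
#' @param sex `"M"` or `"F"`.
#' @param n_boot,level,seed Bootstrap parameters as in [mean_ratio_ci()].
#' @param log_scale If `FALSE`, uses the ratio of arithmetic mean expression
#'   instead.
#' @return List with `point`, `ci_low`, `ci_high`, `n_z`, `n_autosomal`.
#' @export
za_ratio <- function(expr, sex = c("M", "F"), n_boot = 10000, level = 0.95,
                     seed = NULL, log_scale = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  sex <- match.arg(sex)
  if (is.null(expr$chromosome))
    stop("`expr` has no chromosome labels; run assign_chromosomes() first",
         call. = FALSE)
  cols <- sex_columns(expr, sex)
  if (!length(cols)) stop("no samples of sex ", sex, call. = FALSE)
  gene_mean <- rowMeans(expr$values[, cols, drop = FALSE])
  z <- gene_mean[expr$chromosome == "Z"]
  a <- gene_mean[expr$chromosome != "Z"]
  if (!length(z)) stop("no Z-linked genes present", call. = FALSE)
  if (!length(a)) stop("no autosomal genes present", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (log_scale) {
    z <- log2(z[z > 0]); a <- log2(a[a > 0])
    if (length(z) < 2 || length(a) < 2)
      stop("need >= 2 positive-expression genes per class", call. = FALSE)
    point <- 2^(mean(z) - mean(a))
    bz <- rowMeans(matrix(z[sample.int(length(z), length(z) * n_boot,
                                       replace = TRUE)], nrow = n_boot))
    ba <- rowMeans(matrix(a[sample.int(length(a), length(a) * n_boot,
                                       replace = TRUE)], nrow = n_boot))
    boot <- 2^(bz - ba)
  } else {
    point <- mean(z) / mean(a)
    bz <- rowMeans(matrix(z[sample.int(length(z), length(z) * n_boot,
                                       replace = TRUE)], nrow = n_boot))
    ba <- rowMeans(matrix(a[sample.int(length(a), length(a) * n_boot,
                                       replace = TRUE)], nrow = n_boot))
    boot <- bz / ba
  }
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(point = point, ci_low = qs[1], ci_high = qs[2],
       n_z = length(z), n_autosomal = length(a))
}

#' Gaussian kernel density of log2 m:f ratios
#'
#' Wraps [stats::density()] with a Gaussian kernel and Silverman's
#' rule-of-thumb bandwidth (`bw.nrd0`), the display used to reveal, e.g.,
#' bimodality of Z-gene ratios (a compensated mode near 0 and an
#' uncompensated mode near 1 on the log2 scale).
#'
#' @param values Numeric vector of log2 m:f values (>= 2 finite values, not
#'   all identical).
#' @return Data frame with columns `grid` and `density`; the curve
#'   integrates to 1 over its grid.
#' @export
density_log2mf <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2)
    stop("need at least 2 finite values", call. = FALSE)
  if (diff(range(v)) == 0)
    stop("degenerate bandwidth: all values identical", call. = FALSE)
  d <- stats::density(v, bw = "nrd0", kernel = "gaussian")
  data.frame(grid = d$x, density = d$y)
}

#' Classify genes by sex bias of expression
#'
#' Thresholds on the m:f ratio: male-biased above 2, unbiased strictly
#' between 0.8 and 1.2, female-biased below 0.5. The gaps \[0.5, 0.8\] and
#' \[1.2, 2\] are deliberately left unclassified rather than forced into a
#' class.
#'
#' @param mf_ratio Positive numeric vector of m:f ratios.
#' @return Factor with levels `male_biased`, `unbiased`, `female_biased`,
#'   `unclassified`.
#' @examples
#' classify_sex_bias(c(2.5, 1.0, 0.4, 1.5))
#' @export
classify_sex_bias <- function(mf_ratio) {
  if (any(!is.finite(mf_ratio) | mf_ratio <= 0))
    stop("m:f ratios must be positive and finite", call. = FALSE)
  lab <- rep("unclassified", length(mf_ratio))
  lab[mf_ratio > 2] <- "male_biased"
  lab[mf_ratio > 0.8 & mf_ratio < 1.2] <- "unbiased"
  lab[mf_ratio < 0.5] <- "female_biased"
  factor(lab, levels = c("male_biased", "unbiased", "female_biased",
                         "unclassified"))
}

#' One-way ANOVA of expression level on sex-bias class
#'
#' Tests whether expression level in one sex differs among the male-biased,
#' unbiased and female-biased classes (unclassified genes are excluded),
#' with Bonferroni-adjusted pairwise t-tests as the post-hoc comparison.
#'
#' @param expr_level Per-gene log2 expression in one sex.
#' @param classes Per-gene [classify_sex_bias()] labels (same length).
#' @return List with `f_statistic`, `df1`, `df2`, `p_value`, `r_squared`,
#'   `group_means`, `posthoc` (matrix of Bonferroni-adjusted pairwise
#'   p-values) and `n`.
#' @export
bias_expression_anova <- function(expr_level, classes) {
  if (length(expr_level) != length(classes))
    stop("`expr_level` and `classes` must have the same length", call. = FALSE)
  keep <- classes %in% c("male_biased", "unbiased", "female_biased") &
    is.finite(expr_level)
  cl <- droplevels(factor(classes[keep],
                          levels = c("male_biased", "unbiased",
                                     "female_biased")))
  y <- expr_level[keep]
  if (nlevels(cl) < 2)
    stop("need at least two non-empty bias classes", call. = FALSE)
  fit <- stats::aov(y ~ cl)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  posthoc <- stats::pairwise.t.test(y, cl, p.adjust.method = "bonferroni",
                                    pool.sd = TRUE)$p.value
  list(
    f_statistic = an[["F value"]][1],
    df1 = an[["Df"]][1], df2 = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1],
    r_squared = ss[1] / sum(ss),
    group_means = tapply(y, cl, mean),
    posthoc = posthoc,
    n = length(y)
  )
}

#' Sliding-window positional profile of log2 m:f along a chromosome
#'
#' Orders a chromosome's genes by reference position and returns the mean
#' (GC-adjusted, when available) log2 m:f in a sliding window of
#' `window_genes` genes, step one gene — a coarse view of regionally
#' restricted compensation.
#'
#' @param mf_table Data frame with `gene_id`, `chromosome`, `log2_mf` (and
#'   optionally `log2_mf_gc_adjusted`, preferred when present) plus
#'   `position_bp`, or supply `annotation` to join positions.
#' @param chromosome Chromosome label to profile (default `"Z"`).
#' @param window_genes Window size in genes (>= 1).
#' @param annotation Optional annotation data frame with `gene_id` and
#'   `position_bp`.
#' @return Data frame with `position_bp` (window mean position) and
#'   `log2_mf` (window mean), one row per window.
#' @export
positional_mf_profile <- function(mf_table, chromosome = "Z",
                                  window_genes = 10, annotation = NULL) {
  if (!"position_bp" %in% names(mf_table)) {
    if (is.null(annotation))
      stop("`annotation` required when `mf_table` has no position_bp column",
           call. = FALSE)
    idx <- match(mf_table$gene_id, annotation$gene_id)
    mf_table$position_bp <- annotation$position_bp[idx]
  }
  val_col <- if ("log2_mf_gc_adjusted" %in% names(mf_table))
    "log2_mf_gc_adjusted" else "log2_mf"
  d <- mf_table[mf_table$chromosome == chromosome &
                  is.finite(mf_table$position_bp), , drop = FALSE]
  n <- nrow(d)
  if (n < window_genes)
    stop(sprintf("chromosome %s has %d positioned genes, fewer than the window of %d",
                 chromosome, n, window_genes), call. = FALSE)
  d <- d[order(d$position_bp), , drop = FALSE]
  x <- d[[val_col]]
  p <- d$position_bp
  n_win <- n - window_genes + 1
  cx <- c(0, cumsum(x)); cp <- c(0, cumsum(as.numeric(p)))
  i <- seq_len(n_win)
  data.frame(
    position_bp = (cp[i + window_genes] - cp[i]) / window_genes,
    log2_mf = (cx[i + window_genes] - cx[i]) / window_genes
  )
}
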
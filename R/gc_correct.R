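# GC-content bias estimation and removal. Library PCR is more efficient in
# some GC contexts than others, which biases digital expression estimates;
# because GC content differs systematically between avian micro- and
# macro-chromosomes (the Z is relatively GC-poor), an uncorrected GC effect
# distorts chromosome-level m:f comparisons.

#' Fit a linear GC-content effect
#'
#' Ordinary least squares of a per-gene response (log2 expression or
#' log2 m:f) on GC fraction, with the overall F test of the slope.
#'
#' @param response Numeric vector, one value per gene.
#' @param gc Numeric vector of GC fractions, same length.
#' @return Object of class `gc_model`: list with `slope`, `intercept`,
#'   `f_statistic`, `p_value`, `n`.
#' @examples
#' gc <- runif(200, 0.35, 0.65)
#' fit_gc_effect(3 * gc + rnorm(200, sd = 0.1), gc)
#' @export
fit_gc_effect <- function(response, gc) {
  if (length(response) != length(gc))
    stop("`response` and `gc` must have the same length", call. = FALSE)
  ok <- is.finite(response) & is.finite(gc)
  response <- response[ok]; gc <- gc[ok]
  if (length(response) < 3)
    stop("need at least 3 paired finite values to fit a GC effect",
         call. = FALSE)
  if (stats::var(gc) == 0)
    stop("degenerate design: `gc` is constant", call. = FALSE)
  fit <- stats::lm(response ~ gc)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    f_statistic = unname(fs[1]),
    p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    n = length(response)
  ), class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf(
    "GC effect: slope %.4f (log2 per unit GC), F = %.2f, p = %.3g, n = %d\n",
    x$slope, x$f_statistic, x$p_value, x$n))
  invisible(x)
}

#' Remove the GC-content effect from log2 m:f ratios
#'
#' Replaces each gene's log2 m:f by the residual of its OLS regression on GC
#' fraction plus the grand mean, so adjusted values are exactly uncorrelated
#' with GC while the overall mean log2 m:f is preserved. The unadjusted
#' values are kept in `log2_mf_raw`; `log2_mf` itself becomes the adjusted
#' column so downstream chromosome inference picks it up transparently. The
#' operation is idempotent. Genes without a finite GC fraction are dropped
#' (count reported in the `n_dropped` attribute).
#'
#' @param mf_table Data frame from [filter_core_gene_set()] (columns
#'   `gene_id`, `log2_mf`, ...).
#' @param annotation Annotation data frame with `gene_id` and `gc_fraction`
#'   (ignored if `mf_table` already has a `gc_fraction` column).
#' @return `mf_table` with columns `gc_fraction`, `log2_mf_raw`,
#'   `log2_mf_gc_adjusted` and updated `log2_mf`; the fitted [fit_gc_effect()]
#'   model is attached as attribute `gc_model`.
#' @export
remove_gc_effect <- function(mf_table, annotation = NULL) {
  if (!"gc_fraction" %in% names(mf_table)) {
    if (is.null(annotation))
      stop("`annotation` required when `mf_table` has no gc_fraction column",
           call. = FALSE)
    idx <- match(mf_table$gene_id, annotation$gene_id)
    mf_table$gc_fraction <- annotation$gc_fraction[idx]
  }
  ok <- is.finite(mf_table$gc_fraction) & is.finite(mf_table$log2_mf)
  n_dropped <- sum(!ok)
  mf_table <- mf_table[ok, , drop = FALSE]
  model <- fit_gc_effect(mf_table$log2_mf, mf_table$gc_fraction)
  fit <- stats::lm(log2_mf ~ gc_fraction, data = mf_table)
  adjusted <- unname(stats::residuals(fit)) + mean(mf_table$log2_mf)
  if (!"log2_mf_raw" %in% names(mf_table))
    mf_table$log2_mf_raw <- mf_table$log2_mf
  mf_table$log2_mf_gc_adjusted <- adjusted
  mf_table$log2_mf <- adjusted
  mf_table$mf_ratio <- 2^adjusted
  rownames(mf_table) <- NULL
  attr(mf_table, "gc_model") <- model
  attr(mf_table, "n_dropped") <- n_dropped
  mf_table
}

#' Sex-specific GC effects on expression level
#'
#' Convenience report fitting [fit_gc_effect()] separately to male and
#' female mean log2 expression (genes with zero mean in a sex are dropped
#' for that sex). The m:f chromosome inference uses [remove_gc_effect()];
#' these per-sex fits are diagnostics showing which sex carries the bias.
#'
#' @param mf_table Data frame with `mean_m`, `mean_f` and `gc_fraction` (or
#'   supply `annotation` as in [remove_gc_effect()]).
#' @param annotation Optional annotation with `gc_fraction`.
#' @return Named list of two `gc_model` objects (`male`, `female`).
#' @export
gc_effect_by_sex <- function(mf_table, annotation = NULL) {
  if (!"gc_fraction" %in% names(mf_table)) {
    if (is.null(annotation))
      stop("`annotation` required when `mf_table` has no gc_fraction column",
           call. = FALSE)
    idx <- match(mf_table$gene_id, annotation$gene_id)
    mf_table$gc_fraction <- annotation$gc_fraction[idx]
  }
  fit_one <- function(v) {
    pos <- v > 0 & is.finite(v)
    fit_gc_effect(log2(v[pos]), mf_table$gc_fraction[pos])
  }
  list(male = fit_one(mf_table$mean_m), female = fit_one(mf_table$mean_f))
}
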
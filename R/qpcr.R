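# Z-linkage verification from qPCR copy-number assays. A Z-linked locus has
# two template copies in ZZ males and one in ZW females, so its
# concentration relative to an autosomal control is expected to show a
# male-to-female ratio of 2 (vs 1 for an autosomal locus); amplification
# efficiency differences shift the absolute values but not this ratio,
# which is why the m:f ratio is the decisive measure.

#' Relative concentration from the delta-Ct method
#'
#' `concentration = 2^-(ct_target - ct_control)`. Vectorised.
#'
#' @param ct_target Replicate-mean Ct of the target locus.
#' @param ct_control Replicate-mean Ct of the control gene in the same
#'   sample.
#' @return Relative concentration(s), unitless.
#' @examples
#' delta_ct_concentration(21, 20)  # one extra cycle = half the template
#' @export
delta_ct_concentration <- function(ct_target, ct_control) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_control)))
    stop("Ct values must be finite", call. = FALSE)
  2^-(ct_target - ct_control)
}

#' Per-sample relative concentrations for a whole plate
#'
#' Averages replicate Ct values per (sample, gene, locus), then normalises
#' every target locus to the sample's control gene via
#' [delta_ct_concentration()]. Replicate-level Ct standard deviation is
#' returned as QC but not propagated.
#'
#' @param plate Plate data frame (see [read_qpcr_plate()] or
#'   [simulate_qpcr()]).
#' @param control_gene_id Identifier of the autosomal normalising gene; must
#'   be measured in every sample.
#' @return Data frame with one row per (sample, target gene, locus):
#'   `sample_id`, `sex`, `gene_id`, `locus`, `mean_ct`, `ct_sd`,
#'   `concentration`.
#' @export
plate_concentrations <- function(plate, control_gene_id) {
  ct_cols <- grep("^ct[0-9]+$", names(plate), value = TRUE)
  if (!length(ct_cols))
    stop("plate has no replicate Ct columns (ct1, ct2, ...)", call. = FALSE)
  reps <- as.matrix(plate[, ct_cols, drop = FALSE])
  n_rep <- rowSums(is.finite(reps))
  if (any(n_rep < 2))
    stop("fewer than 2 replicate Ct values for (",
         plate$sample_id[which(n_rep < 2)[1]], ", ",
         plate$gene_id[which(n_rep < 2)[1]], ")", call. = FALSE)
  mean_ct <- rowMeans(reps, na.rm = TRUE)
  ct_sd <- apply(reps, 1, stats::sd, na.rm = TRUE)
  is_ctrl <- plate$gene_id == control_gene_id
  if (!any(is_ctrl))
    stop("control gene '", control_gene_id, "' not found on the plate",
         call. = FALSE)
  ctrl_ct <- tapply(mean_ct[is_ctrl], plate$sample_id[is_ctrl], mean)
  samples <- unique(plate$sample_id)
  missing_ctrl <- setdiff(samples, names(ctrl_ct))
  if (length(missing_ctrl))
    stop("control gene '", control_gene_id, "' missing for sample(s): ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  tgt <- !is_ctrl
  data.frame(
    sample_id = plate$sample_id[tgt],
    sex = plate$sex[tgt],
    gene_id = plate$gene_id[tgt],
    locus = plate$locus[tgt],
    mean_ct = mean_ct[tgt],
    ct_sd = ct_sd[tgt],
    concentration = delta_ct_concentration(
      mean_ct[tgt], as.numeric(ctrl_ct[plate$sample_id[tgt]])),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Sex comparison of relative concentrations at one locus
#'
#' Pooled-variance two-sample Student t-test of male vs female relative
#' concentrations with `df = n_m + n_f - 2` and a one-sided p-value for the
#' alternative male > female (the direction expected under Z-linkage),
#' plus the m:f ratio of mean concentrations.
#'
#' @param conc_m,conc_f Per-individual relative concentrations (>= 2 each).
#' @return List with `mean_conc_m`, `mean_conc_f`, `mf_ratio`, `t`, `df`,
#'   `p_value`.
#' @export
locus_mf_test <- function(conc_m, conc_f) {
  n_m <- length(conc_m); n_f <- length(conc_f)
  if (n_m < 2 || n_f < 2)
    stop("need at least 2 samples per sex", call. = FALSE)
  mm <- mean(conc_m); mf <- mean(conc_f)
  df <- n_m + n_f - 2
  sp2 <- (sum((conc_m - mm)^2) + sum((conc_f - mf)^2)) / df
  se <- sqrt(sp2 * (1 / n_m + 1 / n_f))
  if (se == 0) {
    t <- if (mm == mf) 0 else sign(mm - mf) * Inf
  } else {
    t <- (mm - mf) / se
  }
  p <- stats::pt(t, df, lower.tail = FALSE)
  list(mean_conc_m = mm, mean_conc_f = mf, mf_ratio = mm / mf,
       t = t, df = df, p_value = p)
}

#' Per-locus sex tests for a whole plate
#'
#' Applies [locus_mf_test()] to every (gene, locus) combination of a
#' concentration table.
#'
#' @param conc Data frame from [plate_concentrations()].
#' @return Data frame with one row per locus: `gene_id`, `locus`,
#'   `mean_conc_f`, `mean_conc_m`, `mf_ratio`, `t`, `df`, `p_value`.
#' @export
locus_mf_tests <- function(conc) {
  key <- interaction(conc$gene_id, conc$locus, drop = TRUE, sep = "\r")
  out <- lapply(split(conc, key), function(d) {
    res <- locus_mf_test(d$concentration[d$sex == "M"],
                         d$concentration[d$sex == "F"])
    data.frame(gene_id = d$gene_id[1], locus = d$locus[1],
               mean_conc_f = res$mean_conc_f, mean_conc_m = res$mean_conc_m,
               mf_ratio = res$mf_ratio, t = res$t, df = res$df,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gene_id, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call Z-linkage for one gene from its locus results
#'
#' A gene is called `Z_linked` when every locus shows a significant male
#' excess (`p < alpha`) with an m:f ratio at or above `ratio_boundary`
#' (default 1.5, the midpoint between the autosomal expectation of 1 and
#' the Z expectation of 2); `autosomal` when every locus has a ratio below
#' the boundary and `p >= alpha`; `ambiguous` otherwise.
#'
#' @param locus_results Data frame of one gene's loci with columns
#'   `mf_ratio` and `p_value` (e.g. rows of [locus_mf_tests()]).
#' @param alpha Per-locus significance threshold.
#' @param ratio_boundary Ratio boundary between the autosomal and Z calls.
#' @return List with `call` (one of `"Z_linked"`, `"autosomal"`,
#'   `"ambiguous"`) and `n_loci`.
#' @export
call_z_linkage <- function(locus_results, alpha = 0.05, ratio_boundary = 1.5) {
  stopifnot(all(c("mf_ratio", "p_value") %in% names(locus_results)))
  if (!nrow(locus_results))
    stop("need at least one locus", call. = FALSE)
  z_like <- locus_results$p_value < alpha &
    locus_results$mf_ratio >= ratio_boundary
  a_like <- locus_results$p_value >= alpha &
    locus_results$mf_ratio < ratio_boundary
  call <- if (all(z_like)) "Z_linked" else if (all(a_like)) "autosomal"
          else "ambiguous"
  list(call = call, n_loci = nrow(locus_results))
}

#' Call Z-linkage for every gene in a locus-results table
#'
#' @param locus_results Data frame with per-locus `mf_ratio` and `p_value`.
#' @param gene_col Column identifying the gene (use a distinct entry column
#'   when one identifier labels several independently assayed candidates).
#' @param alpha,ratio_boundary Passed to [call_z_linkage()].
#' @return Data frame with one row per gene: the grouping value, `call`,
#'   `n_loci`.
#' @export
call_z_linkage_all <- function(locus_results, gene_col = "gene_id",
                               alpha = 0.05, ratio_boundary = 1.5) {
  stopifnot(gene_col %in% names(locus_results))
  out <- lapply(split(locus_results, locus_results[[gene_col]]), function(d) {
    res <- call_z_linkage(d, alpha = alpha, ratio_boundary = ratio_boundary)
    df <- data.frame(d[[gene_col]][1], call = res$call, n_loci = res$n_loci,
                     stringsAsFactors = FALSE)
    names(df)[1] <- gene_col
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank candidate control genes
#'
#' A good normalising gene for the copy-number assay is autosomal (mean m:f
#' ratio of its raw signal near 1) and stable (small Ct standard deviation
#' across samples). Candidates are ranked by |mean m:f - 1| ascending with
#' Ct variability as the tie-breaker; both criteria are reported. The raw
#' per-gene m:f here is `2^(mean female Ct - mean male Ct)` — no control
#' normalisation is available yet at this stage.
#'
#' @param plate Plate data frame (replicate Ct columns `ct1`, ...).
#' @param candidates Optional character vector restricting the genes ranked.
#' @return Data frame ordered best-first: `gene_id`, `mf_ratio`, `ct_sd`,
#'   `rank`.
#' @export
choose_control_gene <- function(plate, candidates = NULL) {
  ct_cols <- grep("^ct[0-9]+$", names(plate), value = TRUE)
  mean_ct <- rowMeans(as.matrix(plate[, ct_cols, drop = FALSE]), na.rm = TRUE)
  d <- data.frame(gene_id = plate$gene_id, sample_id = plate$sample_id,
                  sex = plate$sex, mean_ct = mean_ct,
                  stringsAsFactors = FALSE)
  if (!is.null(candidates)) d <- d[d$gene_id %in% candidates, , drop = FALSE]
  if (length(unique(d$gene_id)) < 2)
    stop("need at least 2 candidate genes", call. = FALSE)
  per_gene <- lapply(split(d, d$gene_id), function(g) {
    sample_ct <- tapply(g$mean_ct, g$sample_id, mean)
    sample_sex <- tapply(g$sex, g$sample_id, `[`, 1)
    mf <- 2^(mean(sample_ct[sample_sex == "F"]) -
               mean(sample_ct[sample_sex == "M"]))
    data.frame(gene_id = g$gene_id[1], mf_ratio = mf,
               ct_sd = stats::sd(sample_ct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out <- out[order(abs(out$mf_ratio - 1), out$ct_sd), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Amplification efficiency from a serial-dilution standard curve
#'
#' Least-squares slope of mean Ct against log10 template amount;
#' `efficiency = 10^(-1/slope) - 1` (1.0 = perfect per-cycle doubling,
#' slope -3.32).
#'
#' @param template_ng Template amounts of the dilution series (>= 3 points
#'   spanning >= 2 log10 units).
#' @param ct Mean Ct per dilution point.
#' @return List with `efficiency`, `slope`, `r_squared`.
#' @examples
#' eff <- efficiency_from_dilution(c(100, 10, 1, 0.1),
#'                                 c(20, 23.32, 26.64, 29.97))
#' eff$efficiency  # ~1.0
#' @export
efficiency_from_dilution <- function(template_ng, ct) {
  if (length(template_ng) != length(ct) || length(ct) < 3)
    stop("need >= 3 paired dilution points", call. = FALSE)
  if (any(template_ng <= 0))
    stop("template amounts must be positive", call. = FALSE)
  lt <- log10(template_ng)
  if (diff(range(lt)) < 2)
    stop("dilution series must span at least 2 log10 units", call. = FALSE)
  fit <- stats::lm(ct ~ lt)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("non-negative slope: more template must reduce Ct", call. = FALSE)
  # perfect standard curves are legitimate; silence the exact-fit warning
  sm <- suppressWarnings(summary(fit))
  list(efficiency = 10^(-1 / slope) - 1, slope = slope,
       r_squared = sm$r.squared)
}

#' Fisher exact test for excess synteny disruption
#'
#' Compares the number of genes whose focal-species chromosome disagrees
#' with the orthology-predicted chromosome against a background rate of
#' inter-chromosomal movement (e.g. between two reference species), on the
#' 2x2 table `[[observed_moved, observed_stayed], [background_moved,
#' background_stayed]]`. Both sidedness variants are returned; the
#' directional question ("did more genes move than expected?") uses the
#' one-sided (greater) tail.
#'
#' @param observed_moved,observed_total Counts in the tested gene set.
#' @param background_moved,background_total Counts in the background set.
#' @return List with `p_one_sided`, `p_two_sided` and the 2x2 `table`.
#' @export
synteny_disruption_test <- function(observed_moved, observed_total,
                                    background_moved, background_total) {
  counts <- c(observed_moved, observed_total, background_moved,
              background_total)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (observed_moved > observed_total || background_moved > background_total)
    stop("moved count exceeds total", call. = FALSE)
  tab <- matrix(c(observed_moved, observed_total - observed_moved,
                  background_moved, background_total - background_moved),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "background"),
                                c("moved", "stayed")))
  list(
    p_one_sided = stats::fisher.test(tab, alternative = "greater")$p.value,
    p_two_sided = stats::fisher.test(tab, alternative = "two.sided")$p.value,
    table = tab
  )
}

#' Consistency of PCR product lengths with expected intron lengths
#'
#' When a gene has genuinely moved (rather than retrotransposed), amplifying
#' across exon-exon junctions from genomic DNA yields products whose
#' lengths track the reference species' intron lengths. OLS of observed
#' amplicon length on expected length.
#'
#' @param observed_product_bp Observed amplicon lengths (>= 3 junctions).
#' @param expected_with_intron_bp Expected lengths including the reference
#'   intron.
#' @return List with `r_squared`, `p_value` (of the slope), `slope`.
#' @export
intron_length_check <- function(observed_product_bp, expected_with_intron_bp) {
  if (length(observed_product_bp) != length(expected_with_intron_bp) ||
      length(observed_product_bp) < 3)
    stop("need >= 3 paired junction lengths", call. = FALSE)
  fit <- stats::lm(observed_product_bp ~ expected_with_intron_bp)
  sm <- suppressWarnings(summary(fit))
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       slope = unname(stats::coef(fit)[2]))
}
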
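# From read counts to a filtered core gene set with per-gene m:f ratios.

#' Compute RPKM from read counts
#'
#' `RPKM[g, s] = 1e9 * C[g, s] / (N_s * L_g)` where `C` are read counts,
#' `N_s` the sample's library size (total mapped reads, from the sample
#' sheet) and `L_g` the gene's exon length in bp.
#'
#' @param expr An [expression_matrix()] with `unit = "counts"` whose sample
#'   sheet carries `library_size`.
#' @param annotation Annotation data frame with `gene_id` and
#'   `exon_length_bp` covering every gene in `expr`.
#' @return An [expression_matrix()] with `unit = "rpkm"`.
#' @examples
#' # 10 reads on a 1 kb gene in a library of 1e6 reads -> RPKM 10
#' v <- matrix(c(10, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), sex = c("M", "F"),
#'                     group = "x", library_size = 1e6)
#' ann <- data.frame(gene_id = "g1", exon_length_bp = 1000)
#' compute_rpkm(expression_matrix(v, sheet, "counts"), ann)$values
#' @export
compute_rpkm <- function(expr, annotation) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "counts")
    stop("`expr` must hold read counts, not ", expr$unit, call. = FALSE)
  if (is.null(expr$samples$library_size))
    stop("sample sheet has no `library_size` column", call. = FALSE)
  genes <- rownames(expr$values)
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx))
    stop("annotation is missing gene(s): ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  len <- annotation$exon_length_bp[idx]
  if (any(!is.finite(len) | len < 1))
    stop("non-positive exon_length_bp for gene ",
         genes[which(!is.finite(len) | len < 1)[1]], call. = FALSE)
  n <- expr$samples$library_size
  if (any(!is.finite(n) | n <= 0))
    stop("non-positive library_size for sample ",
         expr$samples$sample_id[which(!is.finite(n) | n <= 0)[1]],
         call. = FALSE)
  rpkm <- sweep(expr$values, 2, n, "/")
  rpkm <- sweep(rpkm, 1, len, "/") * 1e9
  expression_matrix(rpkm, expr$samples, unit = "rpkm",
                    chromosome = expr$chromosome)
}

#' Attach chromosome labels via one-to-one orthology
#'
#' Restricts the orthology map to `one2one` rows and transfers the reference
#' species' chromosome label to each focal gene. Genes without a one-to-one
#' orthologue are dropped; their number is recorded in the result's
#' `n_dropped` element.
#'
#' @param expr An [expression_matrix()].
#' @param orthology Data frame with columns `focal_gene_id`,
#'   `reference_chromosome`, `relationship` (see [read_orthology()]).
#' @return `expr` subset to mapped genes, with `chromosome` filled in.
#' @export
assign_chromosomes <- function(expr, orthology) {
  stopifnot(inherits(expr, "expr_matrix"))
  one <- orthology[orthology$relationship == "one2one", , drop = FALSE]
  if (anyDuplicated(one$focal_gene_id))
    stop("duplicate focal_gene_id among one2one orthologues: ",
         one$focal_gene_id[duplicated(one$focal_gene_id)][1], call. = FALSE)
  genes <- rownames(expr$values)
  keep <- genes %in% one$focal_gene_id
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no gene has a one2one orthologue; result is empty")
  }
  out <- subset_genes(expr, keep)
  idx <- match(rownames(out$values), one$focal_gene_id)
  out$chromosome <- as.character(one$reference_chromosome[idx])
  out$n_dropped <- n_dropped
  out
}

#' Filter to a core gene set and tabulate per-gene m:f ratios
#'
#' Shallow sequencing makes per-gene expression estimates noisy; the core
#' gene set keeps a gene only if (i) its expression exceeds a mean
#' expression level in at least `min_samples_per_sex` males *and* as many
#' females, and (ii) the absolute log2 m:f ratio (male mean over female
#' mean) does not exceed `log2_mf_bound`. The reference mean in (i) is,
#' by default, each individual's own mean *log2* expression over its
#' expressed genes (`threshold = "per_individual_log"`, i.e. the geometric
#' mean, which sits near the median of a skewed expression distribution
#' and retains roughly half the genes per individual); alternatives are the
#' individual's arithmetic mean (`"per_individual"`, a much higher bar on
#' skewed data) and the grand mean of the matrix (`"global"`). None of the
#' options needs cross-sample normalisation.
#'
#' @param expr An [expression_matrix()] (RPKM recommended) with both sexes
#'   present in the sample sheet.
#' @param min_samples_per_sex Minimum above-mean individuals per sex.
#' @param log2_mf_bound Bound on |log2(m:f)|.
#' @param threshold Reference mean for "above mean expression" (see above).
#' @return List with `expr` (the retained subset), `mf_table` (data frame
#'   `gene_id`, `chromosome`, `mean_m`, `mean_f`, `mf_ratio`, `log2_mf`),
#'   `n_input` and `n_retained`.
#' @export
filter_core_gene_set <- function(expr, min_samples_per_sex = 2,
                                 log2_mf_bound = 4,
                                 threshold = c("per_individual_log",
                                               "per_individual", "global")) {
  stopifnot(inherits(expr, "expr_matrix"))
  threshold <- match.arg(threshold)
  m_cols <- sex_columns(expr, "M")
  f_cols <- sex_columns(expr, "F")
  if (!length(m_cols) || !length(f_cols))
    stop("both sexes must be present in the sample sheet", call. = FALSE)
  v <- expr$values
  above <- switch(threshold,
    per_individual_log = {
      thr <- apply(v, 2, function(col) {
        pos <- col[col > 0]
        if (!length(pos)) Inf else 2^mean(log2(pos))
      })
      sweep(v, 2, thr, ">")
    },
    per_individual = sweep(v, 2, colMeans(v), ">"),
    global = v > mean(v)
  )
  enough <- rowSums(above[, m_cols, drop = FALSE]) >= min_samples_per_sex &
    rowSums(above[, f_cols, drop = FALSE]) >= min_samples_per_sex
  mean_m <- rowMeans(v[, m_cols, drop = FALSE])
  mean_f <- rowMeans(v[, f_cols, drop = FALSE])
  log2_mf <- log2(mean_m / mean_f)
  keep <- enough & is.finite(log2_mf) & abs(log2_mf) <= log2_mf_bound
  mf_table <- data.frame(
    gene_id = rownames(v)[keep],
    chromosome = if (!is.null(expr$chromosome)) expr$chromosome[keep]
                 else rep(NA_character_, sum(keep)),
    mean_m = mean_m[keep], mean_f = mean_f[keep],
    mf_ratio = (mean_m / mean_f)[keep],
    log2_mf = log2_mf[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(expr = subset_genes(expr, keep), mf_table = mf_table,
       n_input = nrow(v), n_retained = sum(keep))
}
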
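# Cross-species comparison of sex-biased expression over shared orthologues.

#' Collapse probe-level m:f ratios to gene level
#'
#' Microarray datasets report ratios per probe; where several probes map to
#' one gene the per-gene m:f is their arithmetic mean. Probes mapping to
#' more than one gene are rejected.
#'
#' @param probe_mf Data frame with columns `probe_id` and `mf_ratio`.
#' @param probe_to_gene Data frame with columns `probe_id` and `gene_id`
#'   (each probe mapping to at most one gene).
#' @param species Optional species label added as a column.
#' @param gene_chromosome Optional data frame (`gene_id`, `chromosome`) to
#'   attach chromosome labels.
#' @return Data frame with one row per gene: `species` (if given),
#'   `gene_id`, `mf_ratio`, `chromosome` (if given).
#' @export
collapse_probe_ids <- function(probe_mf, probe_to_gene, species = NULL,
                               gene_chromosome = NULL) {
  stopifnot(all(c("probe_id", "mf_ratio") %in% names(probe_mf)),
            all(c("probe_id", "gene_id") %in% names(probe_to_gene)))
  multi <- unique(probe_to_gene$probe_id[duplicated(probe_to_gene$probe_id)])
  if (length(multi)) {
    bad <- probe_to_gene[probe_to_gene$probe_id %in% multi, ]
    if (any(tapply(bad$gene_id, bad$probe_id,
                   function(g) length(unique(g))) > 1))
      stop("probe(s) map to multiple genes: ",
           paste(utils::head(multi, 5), collapse = ", "), call. = FALSE)
    probe_to_gene <- probe_to_gene[!duplicated(probe_to_gene$probe_id), ]
  }
  m <- merge(probe_mf, probe_to_gene, by = "probe_id")
  agg <- stats::aggregate(mf_ratio ~ gene_id, data = m, FUN = mean)
  agg <- agg[order(agg$gene_id), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(gene_chromosome))
    agg$chromosome <- gene_chromosome$chromosome[
      match(agg$gene_id, gene_chromosome$gene_id)]
  if (!is.null(species))
    agg <- cbind(species = species, agg, stringsAsFactors = FALSE)
  agg
}

#' Align m:f tables of two or three species over shared orthologues
#'
#' Inner join on `gene_id` (the shared reference namespace), optionally
#' restricted to Z-linked or autosomal genes, returning a genes-by-species
#' matrix of m:f ratios with rows sorted by gene id.
#'
#' @param tables Named list of 2 or 3 data frames, each with `gene_id`,
#'   `mf_ratio` and (for subsetting) `chromosome`; list names are the
#'   species labels unless the tables carry a `species` column.
#' @param subset One of `"all"`, `"Z"`, `"autosomes"`.
#' @return Numeric matrix, genes x species; zero rows (with a warning) when
#'   the intersection is empty.
#' @export
intersect_orthologues <- function(tables, subset = c("all", "Z", "autosomes")) {
  subset <- match.arg(subset)
  if (!is.list(tables) || length(tables) < 2 || length(tables) > 3)
    stop("`tables` must be a list of 2 or 3 species tables", call. = FALSE)
  labels <- names(tables)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(seq_along(tables), function(i) {
      sp <- unique(tables[[i]]$species)
      if (length(sp) == 1) as.character(sp) else paste0("species", i)
    }, character(1))
  tables <- lapply(tables, function(t) {
    stopifnot(all(c("gene_id", "mf_ratio") %in% names(t)))
    if (subset != "all") {
      if (!"chromosome" %in% names(t))
        stop("chromosome column required for subset = ", subset, call. = FALSE)
      keep <- if (subset == "Z") t$chromosome == "Z" else t$chromosome != "Z"
      t <- t[keep & !is.na(keep), , drop = FALSE]
    }
    t[!duplicated(t$gene_id), , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  shared <- sort(shared)
  if (!length(shared))
    warning("no genes shared across the species tables")
  out <- matrix(NA_real_, nrow = length(shared), ncol = length(tables),
                dimnames = list(shared, labels))
  for (i in seq_along(tables))
    out[, i] <- tables[[i]]$mf_ratio[match(shared, tables[[i]]$gene_id)]
  out
}

#' Pairwise correlation of m:f ratios across species
#'
#' Pearson (default) or Spearman correlation of per-gene m:f ratios between
#' each pair of species, on the log2 scale by default (which makes the
#' coefficient invariant to per-species multiplicative rescaling). Pairs
#' with fewer than 3 complete observations are set to missing.
#'
#' @param aligned Genes-by-species matrix from [intersect_orthologues()].
#' @param log_scale Correlate log2 ratios (default) or raw ratios.
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `mf_cor` with matrices `r`, `p` (two-sided), `n`,
#'   plus `method` and `log_scale`.
#' @export
correlate_mf <- function(aligned, log_scale = TRUE,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(aligned)
  if (log_scale) {
    m[m <= 0] <- NA
    m <- log2(m)
  }
  k <- ncol(m)
  sp <- colnames(m)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
  diag(r) <- 1
  diag(n) <- colSums(is.finite(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(m[ok, i], m[ok, j], method = method,
                            alternative = "two.sided", exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, method = method,
                 log_scale = log_scale), class = "mf_cor")
}

#' @export
print.mf_cor <- function(x, ...) {
  cat(sprintf("m:f ratio correlations (%s%s)\n", x$method,
              if (x$log_scale) ", log2 scale" else ""))
  print(round(x$r, 3))
  invisible(x)
}

# internal: long-format rows of an mf_cor for TSV output
cor_as_table <- function(cm, subset = "all") {
  sp <- colnames(cm$r)
  k <- length(sp)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rows[[length(rows) + 1]] <- data.frame(
      pair = paste(sp[i], sp[j], sep = "-"), subset = subset,
      n = cm$n[i, j], r = cm$r[i, j], p = cm$p[i, j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
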
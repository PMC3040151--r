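# Readers and writers for the plain-text dialects used throughout:
# tab-separated tables with a header line, '.' for missing values, and a
# comma-separated qPCR plate with one column per replicate Ct.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

read_tsv <- function(path, required = character()) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."),
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene_id`, `chromosome`, `position_bp`,
#' `gc_fraction`, `exon_length_bp` (missing values as `.`).
#'
#' @param path Path to a TSV file.
#' @return Data frame with one row per gene.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path, c("gene_id", "chromosome", "gc_fraction",
                         "exon_length_bp"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ", path, call. = FALSE)
  bad <- which(!is.na(df$gc_fraction) &
                 (df$gc_fraction < 0 | df$gc_fraction > 1))
  if (length(bad))
    stop("gc_fraction outside [0, 1] for gene ", df$gene_id[bad[1]],
         call. = FALSE)
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix TSV has a first column `gene_id` and one column per sample; the
#' sample sheet TSV has columns `sample_id`, `sex`, `group`, `library_size`.
#'
#' @param matrix_path Path to the genes-by-samples TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param unit `"counts"` or `"rpkm"`.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  df <- read_tsv(matrix_path, "gene_id")
  samples <- read_tsv(sample_sheet_path, c("sample_id", "sex", "group"))
  values <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(values) <- df$gene_id
  storage.mode(values) <- "double"
  expression_matrix(values, samples, unit = unit)
}

#' Read an orthology map
#'
#' Tab-separated, BioMart-export-like: columns `focal_gene_id`,
#' `reference_gene_id`, `reference_chromosome`, `relationship` (values
#' `one2one` or `other`; missing fields as `.`).
#'
#' @param path Path to a TSV file.
#' @return Data frame with one row per orthology pair.
#' @export
read_orthology <- function(path) {
  df <- read_tsv(path, c("focal_gene_id", "reference_gene_id",
                         "reference_chromosome", "relationship"))
  df$reference_chromosome <- as.character(df$reference_chromosome)
  df
}

#' Read a qPCR plate
#'
#' Comma-separated with header `sample_id,sex,group,gene_id,locus,template_ng,
#' ct1,ct2,ct3` (additional replicate columns `ct4`, ... are allowed; blank
#' cells are missing replicates).
#'
#' @param path Path to a CSV file.
#' @return Data frame with one row per (sample, gene, locus).
#' @export
read_qpcr_plate <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "gene_id", "locus")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(grep("^ct[0-9]+$", names(df))))
    stop(path, " has no replicate Ct columns (ct1, ct2, ...)", call. = FALSE)
  df
}

#' Published qPCR copy-number results for 21 candidate Z-linked crow genes
#'
#' Per-locus relative concentrations (normalised to an autosomal control gene)
#' for 21 candidate Z-linked genes assayed by qPCR in 4 male and 4 female
#' European crows, as published: mean female (`conc_f`) and male (`conc_m`)
#' concentration, their ratio (`mf_ratio`), the pooled two-sample t statistic
#' and its one-sided p-value at 6 degrees of freedom. One gene id appears in
#' two separate table entries in the published source; the `entry` column
#' therefore indexes the 21 assayed candidates.
#'
#' @return Data frame with columns `entry`, `gene_id`, `locus`, `conc_f`,
#'   `conc_m`, `mf_ratio`, `t`, `p_value`.
#' @examples
#' loci <- qpcr_reference_loci()
#' calls <- call_z_linkage_all(loci, gene_col = "entry")
#' table(calls$call)
#' @export
qpcr_reference_loci <- function() {
  path <- system.file("extdata", "crow_qpcr_loci.tsv", package = "zdosage",
                      mustWork = TRUE)
  read_tsv(path, c("entry", "gene_id", "locus", "conc_f", "conc_m",
                   "mf_ratio", "t", "p_value"))
}
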
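#' Construct an expression matrix with its sample sheet
#'
#' Lightweight container pairing a genes-by-samples matrix of non-negative
#' values (read counts or RPKM) with a sample sheet carrying sex labels,
#' grouping and library sizes. Columns of `values` are reordered to match the
#' sample sheet.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be non-negative.
#' @param samples Data frame with columns `sample_id`, `sex` (one of `"M"`,
#'   `"F"`), `group` (free label) and `library_size` (positive; total mapped
#'   reads, required to compute RPKM from counts).
#' @param unit Either `"counts"` or `"rpkm"`.
#' @param chromosome Optional character vector of chromosome labels, one per
#'   gene (usually attached later by [assign_chromosomes()]).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `unit` and (possibly `NULL`) `chromosome`.
#' @examples
#' v <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     sex = c("M", "M", "F", "F"),
#'                     group = "demo", library_size = 1e6)
#' expression_matrix(v, sheet, unit = "counts")
#' @export
expression_matrix <- function(values, samples, unit = c("counts", "rpkm"),
                              chromosome = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in `values`", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("`values` must be finite and non-negative", call. = FALSE)
  req <- c("sample_id", "sex", "group")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(samples$sex %in% c("M", "F")))
    stop("sample sheet `sex` must be 'M' or 'F'", call. = FALSE)
  absent <- setdiff(samples$sample_id, colnames(values))
  if (length(absent))
    stop("sample(s) in sheet but not in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!is.null(chromosome) && length(chromosome) != nrow(values))
    stop("`chromosome` must have one label per gene", call. = FALSE)
  values <- values[, samples$sample_id, drop = FALSE]
  structure(
    list(values = values, samples = as.data.frame(samples), unit = unit,
         chromosome = if (!is.null(chromosome)) as.character(chromosome)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("  sexes: %d M, %d F\n",
              sum(x$samples$sex == "M"), sum(x$samples$sex == "F")))
  if (!is.null(x$chromosome))
    cat(sprintf("  chromosomes: %d (%s)\n",
                length(unique(x$chromosome)),
                paste(utils::head(sort(unique(x$chromosome)), 6),
                      collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# internal: subset genes, keeping sheet and chromosome in sync
subset_genes <- function(expr, keep) {
  expr$values <- expr$values[keep, , drop = FALSE]
  if (!is.null(expr$chromosome)) expr$chromosome <- expr$chromosome[keep]
  expr
}

# internal: column indices for one sex
sex_columns <- function(expr, sex) {
  which(expr$samples$sex == sex)
}
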
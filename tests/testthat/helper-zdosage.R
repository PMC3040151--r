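# Shared fixture builders; everything is constructed in code.

# minimal expression matrix: genes x (n_m males + n_f females)
make_expr <- function(values, n_m = 2, n_f = 2, unit = "rpkm",
                      library_size = 1e6, chromosome = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(n))
  ids <- c(sprintf("m%d", seq_len(n_m)), sprintf("f%d", seq_len(n_f)))
  colnames(values) <- ids
  sheet <- data.frame(sample_id = ids,
                      sex = rep(c("M", "F"), c(n_m, n_f)),
                      group = "g", library_size = library_size,
                      stringsAsFactors = FALSE)
  expression_matrix(values, sheet, unit = unit, chromosome = chromosome)
}

# annotation covering an expr_matrix with constant defaults
make_annotation <- function(expr, exon_length_bp = 1000, gc_fraction = 0.5) {
  data.frame(gene_id = rownames(expr$values),
             chromosome = if (!is.null(expr$chromosome)) expr$chromosome
                          else "1",
             position_bp = seq_len(nrow(expr$values)) * 1000L,
             gc_fraction = gc_fraction, exon_length_bp = exon_length_bp,
             stringsAsFactors = FALSE)
}

# independent hypergeometric oracle for the 2x2 one-sided exact test,
# written from factorial identities only
hypergeom_p_greater <- function(om, ot, bm, bt) {
  moved <- om + bm
  total <- ot + bt
  log_choose <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  ks <- max(0, moved - bt):min(ot, moved)
  probs <- exp(log_choose(ot, ks) + log_choose(bt, moved - ks) -
                 log_choose(total, moved))
  sum(probs[ks >= om])
}

# default-noise simulation helper used by several suites
quick_sim <- function(seed, d = 0, ...) {
  simulate_expression(sim_config(compensation_degree = d, seed = seed, ...))
}
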
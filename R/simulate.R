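# Synthetic-data generators with known ground truth. Every downstream stage
# of the package can be validated against the truth tables these produce:
# the generators encode the biology being modelled (two Z doses in males vs
# one in females, a tunable degree of female up-regulation, GC-correlated
# expression bias, shallow read coverage) rather than read-level realism.

chk_field <- function(cond, field, msg) {
  if (!isTRUE(cond))
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Configuration for the RNA-seq expression simulator
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' shallow-coverage brain transcriptome of a wild bird with 4 individuals per
#' sex, ~3550 genes across ten autosomes plus the Z, and roughly 10 reads per
#' gene and individual.
#'
#' @param n_autosomal_genes Genes per autosome (>= 1).
#' @param autosome_labels Character vector of autosome names.
#' @param n_z_genes Number of Z-linked genes (>= 1).
#' @param n_males,n_females Individuals per sex (>= 1).
#' @param compensation_degree Degree of dosage compensation `d` in \[0, 1\]:
#'   female Z dose is `2^d` against the male dose of 2, so the true Z m:f
#'   ratio is `2^(1 - d)` (1 = full compensation, 0 = none). May be a vector
#'   of length `n_z_genes` for position-dependent compensation.
#' @param baseline_log2_expression_mean,baseline_log2_expression_sd Mean and
#'   sd of per-gene baseline expression on the log2 scale.
#' @param dispersion Negative-binomial overdispersion (>= 0); the default
#'   0.2 corresponds to a biological coefficient of variation of ~0.45,
#'   typical for wild outbred individuals of mixed age. Counts are drawn
#'   with `rnbinom(mu, size = 1/dispersion)`; at exactly 0 the generator is
#'   noise-free and returns the expected counts themselves, so ground-truth
#'   ratios are realised exactly.
#' @param mean_reads_per_gene Target mean reads per gene per individual.
#' @param gc_effect_slope_male,gc_effect_slope_female Log2 expression change
#'   per unit GC fraction, applied per sex around the central GC of 0.5.
#' @param z_gc_shift Additive shift of Z-gene GC fractions (the avian Z is
#'   relatively GC-poor; default -0.05).
#' @param seed Integer seed; identical configurations give identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_genes = 340,
                       autosome_labels = as.character(1:10),
                       n_z_genes = 150,
                       n_males = 4, n_females = 4,
                       compensation_degree = 0,
                       baseline_log2_expression_mean = 3,
                       baseline_log2_expression_sd = 1.5,
                       dispersion = 0.2,
                       mean_reads_per_gene = 10,
                       gc_effect_slope_male = 0,
                       gc_effect_slope_female = 0,
                       z_gc_shift = -0.05,
                       seed = 1L) {
  chk_field(length(autosome_labels) >= 1 && !anyDuplicated(autosome_labels),
            "autosome_labels", "need >= 1 distinct labels")
  chk_field(!"Z" %in% autosome_labels, "autosome_labels",
            "'Z' is reserved for the sex chromosome")
  for (f in c("n_autosomal_genes", "n_z_genes", "n_males", "n_females")) {
    v <- get(f)
    chk_field(is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v),
              f, "must be an integer count >= 1")
  }
  chk_field(is.numeric(compensation_degree) &&
              length(compensation_degree) %in% c(1L, n_z_genes) &&
              all(compensation_degree >= 0 & compensation_degree <= 1),
            "compensation_degree",
            "must lie in [0, 1] (length 1 or one value per Z gene)")
  chk_field(is.numeric(dispersion) && length(dispersion) == 1 &&
              dispersion >= 0, "dispersion", "must be >= 0")
  chk_field(is.numeric(mean_reads_per_gene) && mean_reads_per_gene > 0,
            "mean_reads_per_gene", "must be positive")
  chk_field(is.numeric(baseline_log2_expression_sd) &&
              baseline_log2_expression_sd >= 0,
            "baseline_log2_expression_sd", "must be >= 0")
  chk_field(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed", "must be a single integer")
  structure(list(
    n_autosomal_genes = as.integer(n_autosomal_genes),
    autosome_labels = as.character(autosome_labels),
    n_z_genes = as.integer(n_z_genes),
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    compensation_degree = compensation_degree,
    baseline_log2_expression_mean = baseline_log2_expression_mean,
    baseline_log2_expression_sd = baseline_log2_expression_sd,
    dispersion = dispersion,
    mean_reads_per_gene = mean_reads_per_gene,
    gc_effect_slope_male = gc_effect_slope_male,
    gc_effect_slope_female = gc_effect_slope_female,
    z_gc_shift = z_gc_shift,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an RNA-seq count matrix with known dosage-compensation truth
#'
#' Per-gene baseline expression is lognormal; Z-linked genes carry a male
#' dose of 2 and a female dose of `2^d` (true m:f ratio `2^(1-d)`); GC
#' fraction is uniform on \[0.35, 0.65\] (shifted for Z genes) and
#' sex-specific GC slopes act multiplicatively on the log2 scale around
#' GC = 0.5; integer read counts are negative-binomial around
#' library-scaled expected values, with a gene's read yield proportional to
#' its expression level times its exon length (longer transcripts collect
#' more reads at equal molar expression, as in any shotgun cDNA protocol).
#' One global scaling factor maps relative
#' expression to the target read depth, and the sample sheet's
#' `library_size` is the common nominal depth
#' (`n_genes * mean_reads_per_gene`), so with `dispersion = 0` the realised
#' per-gene m:f equals its ground truth exactly, both on counts and after
#' RPKM.
#'
#' @param config A [sim_config()].
#' @return A list of class `dosage_sim` with elements
#'   * `annotation`: data frame `gene_id`, `chromosome`, `position_bp`,
#'     `gc_fraction`, `exon_length_bp`;
#'   * `expr`: an [expression_matrix()] of counts;
#'   * `truth`: data frame of ground truth per gene (`truth_` columns:
#'     chromosome, baseline log2 expression, compensation degree, dose m:f
#'     ratio, expected m:f ratio including GC effects).
#' @examples
#' sim <- simulate_expression(sim_config(n_autosomal_genes = 50,
#'                                       autosome_labels = c("1", "2"),
#'                                       n_z_genes = 20, seed = 7))
#' sim$expr
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  set.seed(config$seed)
  n_a <- config$n_autosomal_genes * length(config$autosome_labels)
  n_z <- config$n_z_genes
  n_genes <- n_a + n_z
  chrom <- c(rep(config$autosome_labels, each = config$n_autosomal_genes),
             rep("Z", n_z))
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  is_z <- chrom == "Z"

  gc <- stats::runif(n_genes, 0.35, 0.65)
  gc[is_z] <- gc[is_z] + config$z_gc_shift
  gc <- pmin(pmax(gc, 0.01), 0.99)
  exon_length <- pmax(200L,
                      as.integer(round(stats::rlnorm(n_genes, log(1500), 0.45))))
  position <- integer(n_genes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- sort(as.integer(round(stats::runif(length(idx), 1, 1.2e8))))
  }

  d <- rep(0, n_genes)
  d[is_z] <- config$compensation_degree  # recycles a scalar, or per-Z vector
  mu <- stats::rnorm(n_genes, config$baseline_log2_expression_mean,
                     config$baseline_log2_expression_sd)

  sex <- c(rep("M", config$n_males), rep("F", config$n_females))
  sample_id <- c(sprintf("m%02d", seq_len(config$n_males)),
                 sprintf("f%02d", seq_len(config$n_females)))
  group <- rep(c("carrion", "hooded"), length.out = length(sex))
  n_samples <- length(sex)

  gc_dev <- gc - 0.5
  log2_level <- matrix(mu, n_genes, n_samples)
  for (s in seq_len(n_samples)) {
    slope <- if (sex[s] == "M") config$gc_effect_slope_male else
      config$gc_effect_slope_female
    log2_level[, s] <- log2_level[, s] + slope * gc_dev
    if (sex[s] == "F") log2_level[is_z, s] <- log2_level[is_z, s] - (1 - d[is_z])
  }

  rel <- 2^log2_level * (exon_length / 1500)
  scale <- config$mean_reads_per_gene * n_genes * n_samples / sum(rel)
  lambda <- rel * scale
  if (config$dispersion == 0) {
    counts <- lambda
  } else {
    counts <- matrix(stats::rnbinom(length(lambda), mu = lambda,
                                    size = 1 / config$dispersion),
                     n_genes, n_samples)
    storage.mode(counts) <- "double"
  }
  dimnames(counts) <- list(gene_id, sample_id)

  lib <- round(n_genes * config$mean_reads_per_gene)
  samples <- data.frame(sample_id = sample_id, sex = sex, group = group,
                        library_size = lib, stringsAsFactors = FALSE)

  m_cols <- sex == "M"
  truth_mf <- rowMeans(2^log2_level[, m_cols, drop = FALSE]) /
    rowMeans(2^log2_level[, !m_cols, drop = FALSE])
  truth <- data.frame(
    gene_id = gene_id,
    truth_chromosome = chrom,
    truth_log2_baseline = mu,
    truth_compensation = ifelse(is_z, d, NA_real_),
    truth_dose_mf = ifelse(is_z, 2^(1 - d), 1),
    truth_mf = truth_mf,
    stringsAsFactors = FALSE
  )
  annotation <- data.frame(
    gene_id = gene_id, chromosome = chrom, position_bp = position,
    gc_fraction = gc, exon_length_bp = exon_length, stringsAsFactors = FALSE
  )
  structure(list(
    annotation = annotation,
    expr = expression_matrix(counts, samples, unit = "counts",
                             chromosome = chrom),
    truth = truth,
    config = config
  ), class = "dosage_sim")
}

#' Configuration for the qPCR plate simulator
#'
#' @param n_z_genes,n_autosomal_genes Numbers of Z-linked and autosomal test
#'   genes (autosomal may be 0; an autosomal control gene is always added).
#' @param n_males,n_females Individuals per sex (>= 2 for the sex t-test).
#' @param replicates Technical replicates per well (>= 2; default triplicate).
#' @param ct_noise_sd Per-replicate Ct noise, in cycles (>= 0).
#' @param efficiency Per-cycle amplification efficiency in (0.8, 1.1\];
#'   1.0 = perfect doubling.
#' @param control_gene_id Identifier for the autosomal normalising gene.
#' @param seed Integer seed.
#' @return A validated list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_z_genes = 20, n_autosomal_genes = 2,
                            n_males = 4, n_females = 4, replicates = 3,
                            ct_noise_sd = 0.15, efficiency = 1.0,
                            control_gene_id = "CTRL01", seed = 1L) {
  for (f in c("n_z_genes", "n_males", "n_females")) {
    v <- get(f)
    chk_field(is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v),
              f, "must be an integer count >= 1")
  }
  chk_field(is.numeric(n_autosomal_genes) && n_autosomal_genes >= 0 &&
              n_autosomal_genes == round(n_autosomal_genes),
            "n_autosomal_genes", "must be an integer count >= 0")
  chk_field(is.numeric(replicates) && replicates >= 2 &&
              replicates == round(replicates),
            "replicates", "must be an integer >= 2")
  chk_field(is.numeric(ct_noise_sd) && ct_noise_sd >= 0,
            "ct_noise_sd", "must be >= 0")
  chk_field(is.numeric(efficiency) && efficiency > 0.8 && efficiency <= 1.1,
            "efficiency", "must lie in (0.8, 1.1]")
  chk_field(is.character(control_gene_id) && length(control_gene_id) == 1 &&
              nzchar(control_gene_id),
            "control_gene_id", "must be a non-empty identifier")
  structure(list(
    n_z_genes = as.integer(n_z_genes),
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    replicates = as.integer(replicates),
    ct_noise_sd = ct_noise_sd, efficiency = efficiency,
    control_gene_id = control_gene_id, seed = as.integer(seed)
  ), class = "qpcr_sim_config")
}

#' Simulate a qPCR plate with known copy-number truth
#'
#' Template copy number is 2 for autosomal genes in both sexes and for
#' Z-linked genes in (ZZ) males, and 1 for Z-linked genes in (ZW) females.
#' Replicate Ct values are `base_ct - log(copies, base = 1 + efficiency)`
#' plus Gaussian noise, so with perfect efficiency the single female Z copy
#' costs exactly one extra cycle.
#'
#' @param config A [qpcr_sim_config()].
#' @return List of class `qpcr_sim` with elements `plate` (one row per
#'   sample x gene, columns `sample_id`, `sex`, `group`, `gene_id`, `locus`,
#'   `template_ng`, `ct1`...) and `truth` (per-gene chromosome and copy
#'   numbers, `truth_` columns).
#' @export
simulate_qpcr <- function(config) {
  if (!inherits(config, "qpcr_sim_config"))
    config <- do.call(qpcr_sim_config, as.list(config))
  set.seed(config$seed)
  gene_id <- c(sprintf("ZG%03d", seq_len(config$n_z_genes)),
               if (config$n_autosomal_genes > 0)
                 sprintf("AG%03d", seq_len(config$n_autosomal_genes)),
               config$control_gene_id)
  chrom <- c(rep("Z", config$n_z_genes),
             rep("A", config$n_autosomal_genes), "A")
  n_genes <- length(gene_id)
  locus <- sample(c("exon2", "exon3", "exon4", "exon5", "3'UTR"),
                  n_genes, replace = TRUE)
  base_ct <- stats::runif(n_genes, 22, 28)

  sex <- c(rep("M", config$n_males), rep("F", config$n_females))
  sample_id <- c(sprintf("m%02d", seq_len(config$n_males)),
                 sprintf("f%02d", seq_len(config$n_females)))
  group <- rep(c("carrion", "hooded"), length.out = length(sex))

  rows <- expand.grid(s = seq_along(sample_id), g = seq_len(n_genes))
  copies <- ifelse(chrom[rows$g] == "Z" & sex[rows$s] == "F", 1, 2)
  ct_mean <- base_ct[rows$g] - log(copies, base = 1 + config$efficiency)
  reps <- matrix(stats::rnorm(nrow(rows) * config$replicates, mean = ct_mean,
                              sd = config$ct_noise_sd),
                 nrow(rows), config$replicates)
  colnames(reps) <- sprintf("ct%d", seq_len(config$replicates))

  plate <- data.frame(
    sample_id = sample_id[rows$s], sex = sex[rows$s], group = group[rows$s],
    gene_id = gene_id[rows$g], locus = locus[rows$g], template_ng = 10,
    stringsAsFactors = FALSE
  )
  plate <- cbind(plate, as.data.frame(reps))
  truth <- data.frame(
    gene_id = gene_id, locus = locus, truth_chromosome = chrom,
    truth_copies_male = 2,
    truth_copies_female = ifelse(chrom == "Z", 1, 2),
    stringsAsFactors = FALSE
  )
  structure(list(plate = plate, truth = truth, config = config),
            class = "qpcr_sim")
}

#' Simulate an orthology map with synteny disruptions
#'
#' Each focal gene's true chromosome equals the reference species' chromosome
#' except for a Bernoulli(`disruption_rate`) fraction whose reference record
#' points to a random different chromosome (the gene moved in one lineage).
#'
#' @param n_genes Number of genes (ignored when `annotation` is given).
#' @param disruption_rate Probability in \[0, 1) that a gene's reference
#'   chromosome disagrees with its focal chromosome.
#' @param seed Integer seed.
#' @param chromosomes Chromosome universe used when no annotation is given.
#' @param annotation Optional annotation data frame (`gene_id`,
#'   `chromosome`); when supplied, focal ids and true chromosomes are taken
#'   from it so the map plugs into a matching expression simulation.
#' @return Data frame with columns `focal_gene_id`, `reference_gene_id`,
#'   `reference_chromosome`, `relationship` plus ground truth
#'   (`truth_focal_chromosome`, `truth_disrupted`).
#' @export
simulate_orthology <- function(n_genes, disruption_rate, seed,
                               chromosomes = c(as.character(1:28), "Z"),
                               annotation = NULL) {
  chk_field(is.numeric(disruption_rate) && disruption_rate >= 0 &&
              disruption_rate < 1, "disruption_rate", "must lie in [0, 1)")
  set.seed(as.integer(seed))
  if (!is.null(annotation)) {
    focal_id <- annotation$gene_id
    true_chrom <- as.character(annotation$chromosome)
    n_genes <- length(focal_id)
    chromosomes <- unique(true_chrom)
  } else {
    chk_field(is.numeric(n_genes) && n_genes >= 1, "n_genes",
              "must be an integer count >= 1")
    n_genes <- as.integer(n_genes)
    focal_id <- sprintf("gene%05d", seq_len(n_genes))
    true_chrom <- sample(chromosomes, n_genes, replace = TRUE)
  }
  disrupted <- stats::runif(n_genes) < disruption_rate
  ref_chrom <- true_chrom
  if (any(disrupted) && length(chromosomes) > 1) {
    ref_chrom[disrupted] <- vapply(true_chrom[disrupted], function(ch)
      sample(setdiff(chromosomes, ch), 1), character(1))
  }
  data.frame(
    focal_gene_id = focal_id,
    reference_gene_id = sprintf("REF%05d", seq_len(n_genes)),
    reference_chromosome = ref_chrom,
    relationship = "one2one",
    truth_focal_chromosome = true_chrom,
    truth_disrupted = disrupted,
    stringsAsFactors = FALSE
  )
}

#' Write a simulated expression dataset to TSV files
#'
#' Writes the dialects the analysis readers consume: `counts.tsv` (gene by
#' sample), `samples.tsv`, `annotation.tsv`, and a `truth.tsv` sidecar whose
#' ground-truth columns carry the `truth_` prefix.
#'
#' @param sim A `dosage_sim` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dosage_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  counts_df <- data.frame(gene_id = rownames(sim$expr$values),
                          sim$expr$values, check.names = FALSE)
  write_tsv(counts_df, paths["counts"])
  write_tsv(sim$expr$samples, paths["samples"])
  write_tsv(sim$annotation, paths["annotation"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
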
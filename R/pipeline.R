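# Pipeline orchestration: run the full dosage-compensation analysis (or the
# qPCR Z-linkage analysis) from a configuration list or YAML file, writing
# TSV/JSON outputs plus a manifest that records the seed, parameters and the
# gene-count funnel at each filtering step.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("`config` must be a list or the path to a YAML file", call. = FALSE)
  config
}

default_opt <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the dosage-compensation pipeline
#'
#' Executes quantification (RPKM, orthology-based chromosome assignment,
#' core gene-set filter), optional GC correction, chromosome-level m:f
#' inference, Z:A ratios per sex, the log2 m:f density, sex-bias
#' classification with the expression-level ANOVA, and (when at least one
#' other species table is configured) the cross-species correlation.
#' Outputs `mf_table.tsv`, `chrom_summary.tsv`, `bias_anova.json`,
#' optionally `cross_species_corr.tsv`, and `manifest.json` in the output
#' directory. Runs with the same configuration and seed are byte-identical.
#'
#' @param config A list, or path to a YAML file, with fields: `counts`,
#'   `sample_sheet`, `annotation`, `orthology` (input TSV paths);
#'   `min_samples_per_sex` (default 2), `log2_mf_bound` (4),
#'   `gc_correction` (TRUE), `alpha` (0.05), `n_boot` (1000), `seed` (1),
#'   `outdir`; optional `species_tables` (named list of per-species m:f TSV
#'   paths with columns `species`, `gene_id`, `mf_ratio`, `chromosome`) and
#'   `focal_species` label (default "focal"); optional `stratify_by_group`
#'   (FALSE) to repeat the chromosome inference within each sample-sheet
#'   group.
#' @param outdir Output directory, overriding `config$outdir`.
#' @return Invisibly, a list with the fitted objects (`mf_table`,
#'   `chrom_mf`, `za`, `anova`, `cross_species`, `manifest`).
#' @export
run_dosage_pipeline <- function(config, outdir = NULL) {
  config <- read_pipeline_config(config)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- default_opt(config, "seed", 1L)
  set.seed(seed)

  for (f in c("counts", "sample_sheet", "annotation", "orthology")) {
    if (is.null(config[[f]]))
      stop("config is missing input path `", f, "`", call. = FALSE)
    if (!file.exists(config[[f]]))
      stop("input file for `", f, "` not found: ", config[[f]],
           call. = FALSE)
  }

  annotation <- run_stage("read_inputs", read_annotation(config$annotation))
  counts <- run_stage("read_inputs",
                      read_expression(config$counts, config$sample_sheet,
                                      unit = "counts"))
  orthology <- run_stage("read_inputs", read_orthology(config$orthology))

  rpkm <- run_stage("rpkm", compute_rpkm(counts, annotation))
  mapped <- run_stage("assign_chromosomes",
                      assign_chromosomes(rpkm, orthology))
  filt <- run_stage("core_gene_set", filter_core_gene_set(
    mapped,
    min_samples_per_sex = default_opt(config, "min_samples_per_sex", 2),
    log2_mf_bound = default_opt(config, "log2_mf_bound", 4)))
  mf_table <- filt$mf_table

  gc_correction <- isTRUE(default_opt(config, "gc_correction", TRUE))
  gc_model <- NULL
  if (gc_correction) {
    mf_table <- run_stage("gc_correction",
                          remove_gc_effect(mf_table, annotation))
    gc_model <- attr(mf_table, "gc_model")
  }

  alpha <- default_opt(config, "alpha", 0.05)
  n_boot <- default_opt(config, "n_boot", 1000)
  chrom <- run_stage("chromosome_regression",
                     chromosome_mf_regression(mf_table, alpha = alpha))
  za <- run_stage("za_ratio", list(
    M = za_ratio(filt$expr, "M", n_boot = n_boot, seed = seed),
    F = za_ratio(filt$expr, "F", n_boot = n_boot, seed = seed + 1L)))
  dens <- run_stage("density", list(
    Z = density_log2mf(mf_table$log2_mf[mf_table$chromosome == "Z"]),
    autosomes = density_log2mf(mf_table$log2_mf[mf_table$chromosome != "Z"])))

  classes <- run_stage("bias_classes", classify_sex_bias(mf_table$mf_ratio))
  anova_res <- run_stage("bias_anova", list(
    male = bias_expression_anova(log2(mf_table$mean_m), classes),
    female = bias_expression_anova(log2(mf_table$mean_f), classes)))

  cross <- NULL
  if (!is.null(config$species_tables) && length(config$species_tables) >= 1) {
    cross <- run_stage("cross_species", {
      focal <- default_opt(config, "focal_species", "focal")
      own <- data.frame(species = focal, gene_id = mf_table$gene_id,
                        mf_ratio = mf_table$mf_ratio,
                        chromosome = mf_table$chromosome,
                        stringsAsFactors = FALSE)
      others <- lapply(config$species_tables, function(p)
        read_tsv(p, c("species", "gene_id", "mf_ratio", "chromosome")))
      tabs <- c(list(own), others)
      names(tabs) <- c(focal, vapply(others, function(t)
        as.character(t$species[1]), character(1)))
      aligned <- intersect_orthologues(tabs[seq_len(min(3, length(tabs)))],
                                       subset = "Z")
      correlate_mf(aligned)
    })
  }

  strat <- NULL
  if (isTRUE(default_opt(config, "stratify_by_group", FALSE))) {
    strat <- run_stage("stratified", {
      groups <- unique(filt$expr$samples$group)
      res <- list()
      for (g in groups) {
        keep <- filt$expr$samples$group == g
        sub <- expression_matrix(
          filt$expr$values[, filt$expr$samples$sample_id[keep], drop = FALSE],
          filt$expr$samples[keep, , drop = FALSE], unit = filt$expr$unit,
          chromosome = filt$expr$chromosome)
        sub_mf <- filter_core_gene_set(
          sub, min_samples_per_sex = default_opt(config,
                                                 "min_samples_per_sex", 2),
          log2_mf_bound = default_opt(config, "log2_mf_bound", 4))$mf_table
        if (gc_correction)
          sub_mf <- remove_gc_effect(sub_mf, annotation)
        res[[g]] <- chromosome_mf_regression(sub_mf, alpha = alpha)
        write_tsv(res[[g]]$summary,
                  file.path(outdir, paste0("chrom_summary_", g, ".tsv")))
      }
      res
    })
  }

  write_tsv(mf_table, file.path(outdir, "mf_table.tsv"))
  write_tsv(chrom$summary, file.path(outdir, "chrom_summary.tsv"))
  anova_json <- list(
    male = anova_res$male[c("f_statistic", "df1", "df2", "p_value",
                            "r_squared", "n")],
    female = anova_res$female[c("f_statistic", "df1", "df2", "p_value",
                                "r_squared", "n")],
    class_counts = as.list(table(classes))
  )
  jsonlite::write_json(anova_json, file.path(outdir, "bias_anova.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cross))
    write_tsv(cor_as_table(cross, subset = "Z"),
              file.path(outdir, "cross_species_corr.tsv"))

  manifest <- list(
    package = "zdosage",
    version = as.character(utils::packageVersion("zdosage")),
    seed = seed,
    parameters = list(
      min_samples_per_sex = default_opt(config, "min_samples_per_sex", 2),
      log2_mf_bound = default_opt(config, "log2_mf_bound", 4),
      gc_correction = gc_correction, alpha = alpha, n_boot = n_boot),
    inputs = config[c("counts", "sample_sheet", "annotation", "orthology")],
    gene_funnel = list(
      genes_in = nrow(counts$values),
      genes_after_orthology = nrow(mapped$values),
      genes_after_filter = filt$n_retained),
    gc_model = if (!is.null(gc_model)) unclass(gc_model),
    global_f_test = list(f = chrom$f_statistic, df1 = chrom$df1,
                         df2 = chrom$df2, p = chrom$p_value),
    za_ratio = list(M = za$M[c("point", "ci_low", "ci_high")],
                    F = za$F[c("point", "ci_low", "ci_high")])
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(mf_table = mf_table, chrom_mf = chrom, za = za,
                 density = dens, anova = anova_res, cross_species = cross,
                 stratified = strat, manifest = manifest))
}

#' Run the qPCR Z-linkage pipeline
#'
#' Reads a plate CSV, computes delta-Ct relative concentrations against the
#' configured control gene, performs the per-locus sex tests and gene-level
#' Z-linkage calls, and writes `locus_results.tsv`, `zlink_calls.tsv` and
#' `manifest.json`.
#'
#' @param config A list, or path to a YAML file, with fields `plate` (CSV
#'   path), `control_gene_id`, and optionally `alpha` (0.05),
#'   `ratio_boundary` (1.5), `seed` (1), `outdir`.
#' @param outdir Output directory, overriding `config$outdir`.
#' @return Invisibly, a list with `concentrations`, `locus_results`,
#'   `calls`, `manifest`.
#' @export
run_qpcr_pipeline <- function(config, outdir = NULL) {
  config <- read_pipeline_config(config)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$plate))
    stop("config is missing input path `plate`", call. = FALSE)
  if (is.null(config$control_gene_id))
    stop("config is missing `control_gene_id`", call. = FALSE)
  seed <- default_opt(config, "seed", 1L)
  set.seed(seed)

  plate <- run_stage("read_plate", read_qpcr_plate(config$plate))
  conc <- run_stage("delta_ct",
                    plate_concentrations(plate, config$control_gene_id))
  loci <- run_stage("locus_tests", locus_mf_tests(conc))
  alpha <- default_opt(config, "alpha", 0.05)
  boundary <- default_opt(config, "ratio_boundary", 1.5)
  calls <- run_stage("z_linkage_calls",
                     call_z_linkage_all(loci, alpha = alpha,
                                        ratio_boundary = boundary))

  write_tsv(loci, file.path(outdir, "locus_results.tsv"))
  write_tsv(calls, file.path(outdir, "zlink_calls.tsv"))
  manifest <- list(
    package = "zdosage",
    version = as.character(utils::packageVersion("zdosage")),
    seed = seed,
    parameters = list(control_gene_id = config$control_gene_id,
                      alpha = alpha, ratio_boundary = boundary),
    inputs = list(plate = config$plate),
    n_loci = nrow(loci),
    calls = as.list(table(calls$call))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(concentrations = conc, locus_results = loci, calls = calls,
                 manifest = manifest))
}

#' Write a bundled synthetic demo dataset
#'
#' Generates a small ground-truthed expression dataset (with matching
#' orthology map) and qPCR plate, writes them to `dir` in the pipeline's
#' input dialects, and returns ready-to-run configuration lists for
#' [run_dosage_pipeline()] and [run_qpcr_pipeline()].
#'
#' @param dir Directory for the demo inputs (created if needed).
#' @param seed Integer seed.
#' @param compensation_degree Degree of dosage compensation simulated.
#' @return List with `dosage_config` and `qpcr_config` (both lists), plus
#'   `truth` tables for reference.
#' @export
write_demo_dataset <- function(dir, seed = 1L, compensation_degree = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(sim_config(
    n_autosomal_genes = 120, autosome_labels = as.character(1:5),
    n_z_genes = 80, compensation_degree = compensation_degree, seed = seed))
  paths <- write_simulation(sim, dir)
  orth <- simulate_orthology(disruption_rate = 0, seed = seed,
                             annotation = sim$annotation)
  orth_path <- file.path(dir, "orthology.tsv")
  write_tsv(orth, orth_path)
  qsim <- simulate_qpcr(qpcr_sim_config(seed = seed))
  plate_path <- file.path(dir, "plate.csv")
  utils::write.csv(qsim$plate, plate_path, row.names = FALSE, quote = FALSE)
  list(
    dosage_config = list(
      counts = unname(paths["counts"]),
      sample_sheet = unname(paths["samples"]),
      annotation = unname(paths["annotation"]),
      orthology = orth_path,
      seed = seed, outdir = file.path(dir, "out")),
    qpcr_config = list(
      plate = plate_path,
      control_gene_id = qsim$config$control_gene_id,
      seed = seed, outdir = file.path(dir, "out_qpcr")),
    truth = list(expression = sim$truth, qpcr = qsim$truth,
                 orthology = orth)
  )
}
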
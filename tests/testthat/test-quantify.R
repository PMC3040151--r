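test_that("RPKM follows its defining formula", {
  v <- matrix(c(10, 0, 50), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expr <- expression_matrix(
    v, data.frame(sample_id = "s1", sex = "M", group = "g",
                  library_size = 1e6),
    unit = "counts")
  ann <- data.frame(gene_id = c("a", "b", "c"),
                    exon_length_bp = c(1000, 500, 2500))
  r1 <- compute_rpkm(expr, ann)
  expect_equal(unname(r1$values["a", 1]), 10)
  expect_equal(unname(r1$values["b", 1]), 0)
  # the full-study library size of 856675 reads over a 2.5 kb gene
  expr$samples$library_size <- 856675
  r2 <- compute_rpkm(expr, ann)
  expect_equal(unname(r2$values["c", 1]), 23.346, tolerance = 1e-4)
})

test_that("RPKM is linear in counts and inverse-linear in length and depth", {
  set.seed(1)
  v <- matrix(rpois(40, 20), 10, 4)
  rownames(v) <- sprintf("g%02d", 1:10)
  expr <- make_expr(v, unit = "counts")
  ann <- make_annotation(expr, exon_length_bp = sample(500:2000, 10))
  base <- compute_rpkm(expr, ann)$values

  expr2 <- expr; expr2$values <- expr$values * 3
  expect_equal(compute_rpkm(expr2, ann)$values, base * 3)

  ann2 <- ann; ann2$exon_length_bp <- ann$exon_length_bp * 2
  expect_equal(compute_rpkm(expr, ann2)$values, base / 2)

  expr3 <- expr; expr3$samples$library_size <- expr$samples$library_size * 4
  expect_equal(compute_rpkm(expr3, ann)$values, base / 4)
})

test_that("RPKM rejects zero library sizes and missing lengths by name", {
  v <- matrix(1, 1, 2, dimnames = list("gX", c("s1", "s2")))
  sheet <- data.frame(sample_id = c("s1", "s2"), sex = c("M", "F"),
                      group = "g", library_size = c(1e6, 0))
  expr <- expression_matrix(v, sheet, unit = "counts")
  ann <- data.frame(gene_id = "gX", exon_length_bp = 100)
  expect_error(compute_rpkm(expr, ann), "s2")
  ann0 <- data.frame(gene_id = "gX", exon_length_bp = 0)
  sheet$library_size <- 1e6
  expr <- expression_matrix(v, sheet, unit = "counts")
  expect_error(compute_rpkm(expr, ann0), "gX")
})

test_that("chromosome assignment keeps one2one orthologues and counts drops", {
  v <- matrix(1, 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  expr <- make_expr(v)
  orth <- data.frame(
    focal_gene_id = sprintf("g%02d", 1:8),
    reference_gene_id = sprintf("r%02d", 1:8),
    reference_chromosome = c(rep("1", 4), rep("Z", 4)),
    relationship = c(rep("one2one", 8)))
  out <- assign_chromosomes(expr, orth)
  expect_equal(nrow(out$values), 8)
  expect_equal(out$n_dropped, 2)
  expect_equal(out$chromosome, c(rep("1", 4), rep("Z", 4)))

  # non-one2one rows are ignored
  orth$relationship[3] <- "other"
  out2 <- assign_chromosomes(expr, orth)
  expect_equal(nrow(out2$values), 7)

  # duplicated focal ids after restriction are an input error
  orth_dup <- rbind(orth, orth[1, ])
  expect_error(assign_chromosomes(expr, orth_dup), "duplicate")

  # empty overlap warns and returns an empty object
  orth_none <- orth
  orth_none$focal_gene_id <- sprintf("x%02d", 1:8)
  expect_warning(out3 <- assign_chromosomes(expr, orth_none), "empty")
  expect_equal(nrow(out3$values), 0)
})

test_that("assigned chromosomes match ground truth for an undisrupted map", {
  sim <- quick_sim(9, d = 0.5)
  orth <- simulate_orthology(disruption_rate = 0, seed = 9,
                             annotation = sim$annotation)
  mapped <- assign_chromosomes(sim$expr, orth)
  truth <- sim$truth$truth_chromosome[match(rownames(mapped$values),
                                            sim$truth$gene_id)]
  expect_identical(mapped$chromosome, truth)
})

test_that("core gene-set filter applies both retention rules", {
  # an abundant balanced gene is kept; a uniformly low gene is not
  v1 <- rbind(g1 = rep(100, 6), g2 = rep(1, 6))
  out1 <- filter_core_gene_set(make_expr(v1, n_m = 3, n_f = 3),
                               threshold = "per_individual")
  expect_identical(out1$mf_table$gene_id, "g1")
  expect_equal(out1$mf_table$log2_mf, 0)
  expect_equal(out1$n_retained, 1)

  # a gene with |log2 m:f| = 5 clears the abundance rule but not the bound
  v2 <- rbind(matrix(10, 5, 6,
                     dimnames = list(sprintf("bg%d", 1:5), NULL)),
              big = c(640, 640, 640, 20, 20, 20))
  expr2 <- make_expr(v2, n_m = 3, n_f = 3)
  out2 <- filter_core_gene_set(expr2, threshold = "per_individual")
  expect_false("big" %in% out2$mf_table$gene_id)
  out2b <- filter_core_gene_set(expr2, log2_mf_bound = 10,
                                threshold = "per_individual")
  expect_true("big" %in% out2b$mf_table$gene_id)
  expect_equal(out2b$mf_table$log2_mf[out2b$mf_table$gene_id == "big"], 5)

  # above the threshold in one male only: fails the >=2-per-sex rule even
  # though all three females clear it
  v3 <- rbind(matrix(10, 5, 6,
                     dimnames = list(sprintf("bg%d", 1:5), NULL)),
              lop = c(40, 5, 5, 40, 40, 40))
  out3 <- filter_core_gene_set(make_expr(v3, n_m = 3, n_f = 3),
                               threshold = "per_individual")
  expect_false("lop" %in% out3$mf_table$gene_id)

  # an empty result is well formed
  v4 <- matrix(5, 2, 6, dimnames = list(c("x1", "x2"), NULL))
  out4 <- filter_core_gene_set(make_expr(v4, n_m = 3, n_f = 3),
                               threshold = "per_individual")
  expect_equal(out4$n_retained, 0)
  expect_equal(nrow(out4$mf_table), 0)
})

test_that("filtering is invariant to gene and sample order", {
  set.seed(42)
  sim <- simulate_expression(sim_config(n_autosomal_genes = 60,
                                        autosome_labels = c("1", "2"),
                                        n_z_genes = 40, seed = 13))
  rpkm <- compute_rpkm(sim$expr, sim$annotation)
  ref <- filter_core_gene_set(rpkm)$mf_table
  gperm <- sample(nrow(rpkm$values))
  sperm <- sample(ncol(rpkm$values))
  shuffled <- expression_matrix(rpkm$values[gperm, sperm],
                                rpkm$samples[sperm, ],
                                unit = "rpkm",
                                chromosome = rpkm$chromosome[gperm])
  out <- filter_core_gene_set(shuffled)$mf_table
  out <- out[match(ref$gene_id, out$gene_id), ]
  rownames(out) <- NULL
  expect_equal(out, ref)
})

test_that("noise-free uncompensated simulation gives log2 m:f of exactly 1 on Z", {
  sim <- simulate_expression(sim_config(
    n_autosomal_genes = 100, autosome_labels = c("1", "2"), n_z_genes = 80,
    compensation_degree = 0, dispersion = 0,
    gc_effect_slope_male = 0, gc_effect_slope_female = 0, seed = 6))
  rpkm <- compute_rpkm(sim$expr, sim$annotation)
  out <- filter_core_gene_set(rpkm)
  z <- out$mf_table$chromosome == "Z"
  expect_gt(sum(z), 0)
  expect_equal(out$mf_table$log2_mf[z], rep(1, sum(z)))
  expect_equal(out$mf_table$log2_mf[!z], rep(0, sum(!z)))
})

test_that("filter requires both sexes", {
  v <- matrix(1, 2, 4, dimnames = list(c("a", "b"), NULL))
  ids <- sprintf("s%d", 1:4)
  colnames(v) <- ids
  sheet <- data.frame(sample_id = ids, sex = "M", group = "g",
                      library_size = 1)
  expr <- expression_matrix(v, sheet, unit = "rpkm")
  expect_error(filter_core_gene_set(expr), "both sexes")
})

test_that("expression tables round-trip through their TSV dialect", {
  sim <- simulate_expression(sim_config(n_autosomal_genes = 20,
                                        autosome_labels = "1",
                                        n_z_genes = 10, seed = 30))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_expression(paths["counts"], paths["samples"], unit = "counts")
  expect_equal(back$values, sim$expr$values)
  expect_equal(back$samples$sex, sim$expr$samples$sex)
  ann <- read_annotation(paths["annotation"])
  expect_equal(ann$gc_fraction, sim$annotation$gc_fraction, tolerance = 1e-12)
  expect_identical(ann$chromosome, sim$annotation$chromosome)
})
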
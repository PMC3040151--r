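test_that("delta-Ct concentrations halve per extra cycle", {
  expect_equal(delta_ct_concentration(20, 20), 1)
  expect_equal(delta_ct_concentration(21, 20), 0.5)
  expect_equal(delta_ct_concentration(19, 20), 2)
  ct <- seq(18, 25, by = 0.5)
  expect_equal(delta_ct_concentration(ct + 1, 20),
               delta_ct_concentration(ct, 20) / 2)
  expect_error(delta_ct_concentration(NA, 20), "finite")
})

test_that("plate concentrations require a control in every sample", {
  qs <- simulate_qpcr(qpcr_sim_config(n_z_genes = 3, n_autosomal_genes = 1,
                                      seed = 31))
  conc <- plate_concentrations(qs$plate, "CTRL01")
  expect_setequal(unique(conc$gene_id),
                  setdiff(unique(qs$plate$gene_id), "CTRL01"))
  expect_error(plate_concentrations(qs$plate, "NOPE"), "NOPE")
  broken <- qs$plate[!(qs$plate$gene_id == "CTRL01" &
                         qs$plate$sample_id == "m01"), ]
  expect_error(plate_concentrations(broken, "CTRL01"), "m01")
})

test_that("the pooled one-sided t reproduces published locus p-values", {
  # printed (t, p) pairs at df = 6 from the reference locus table
  t_vals <- c(0.41, 0.50, 0.53, 0.65, 0.72, 1.17)
  p_vals <- c(0.34855, 0.31822, 0.30709, 0.26995, 0.24832, 0.14404)
  expect_lt(max(abs(pt(t_vals, 6, lower.tail = FALSE) - p_vals)), 1e-3)

  # and locus_mf_test realises the same tail: construct samples with a
  # known pooled t, then compare
  set.seed(3)
  for (i in 1:20) {
    m <- rnorm(4, 1.1, 0.2); f <- rnorm(4, 1.0, 0.2)
    res <- locus_mf_test(m, f)
    expect_equal(res$df, 6)
    expect_equal(res$p_value, pt(res$t, 6, lower.tail = FALSE))
    expect_equal(res$mf_ratio, mean(m) / mean(f))
  }
})

test_that("degenerate locus comparisons are well defined", {
  res <- locus_mf_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 0.5)
  res2 <- locus_mf_test(c(2, 2), c(1, 1))
  expect_equal(res2$p_value, 0)
  expect_error(locus_mf_test(1, c(1, 2)), "2 samples per sex")
})

test_that("locus p-values are uniform under the autosomal null", {
  set.seed(77)
  p <- vapply(1:2000, function(i)
    locus_mf_test(rnorm(4, 1, 0.15), rnorm(4, 1, 0.15))$p_value, numeric(1))
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Z-linkage calls follow the all-loci rule", {
  z <- data.frame(mf_ratio = c(2.03, 2.40), p_value = c(0.00077, 0.00305))
  expect_equal(call_z_linkage(z)$call, "Z_linked")
  a <- data.frame(mf_ratio = c(1.05, 1.14, 1.06),
                  p_value = c(0.34855, 0.14404, 0.26995))
  expect_equal(call_z_linkage(a)$call, "autosomal")
  mix <- data.frame(mf_ratio = c(2.0, 1.0), p_value = c(0.001, 0.9))
  expect_equal(call_z_linkage(mix)$call, "ambiguous")
  expect_equal(call_z_linkage(z)$n_loci, 2)
})

test_that("control-gene ranking puts ratio closeness before stability", {
  mk_rows <- function(gene, ct_m, ct_f) {
    do.call(rbind, lapply(seq_along(c(ct_m, ct_f)), function(i) {
      sexes <- rep(c("M", "F"), c(length(ct_m), length(ct_f)))
      ct <- c(ct_m, ct_f)[i]
      data.frame(sample_id = sprintf("s%d", i), sex = sexes[i],
                 gene_id = gene, locus = "exon1", ct1 = ct, ct2 = ct,
                 ct3 = ct, stringsAsFactors = FALSE)
    }))
  }
  # A: m:f exactly 1, moderate spread; B: biased ratio, tiny spread
  plate <- rbind(mk_rows("A", c(24.8, 25.2), c(24.8, 25.2)),
                 mk_rows("B", c(25, 25), c(25.4, 25.4)))
  ranked <- choose_control_gene(plate)
  expect_equal(ranked$gene_id[1], "A")

  # equal ratios: smaller Ct spread wins
  plate2 <- rbind(mk_rows("C", c(25, 25), c(25, 25)),
                  mk_rows("D", c(24.5, 25.5), c(24.5, 25.5)))
  ranked2 <- choose_control_gene(plate2)
  expect_equal(ranked2$gene_id[1], "C")
  expect_error(choose_control_gene(plate[plate$gene_id == "A", ]),
               "2 candidate")
})

test_that("a low-noise autosomal gene is chosen as control in simulations", {
  hits <- vapply(1:40, function(s) {
    qs <- simulate_qpcr(qpcr_sim_config(n_z_genes = 4, n_autosomal_genes = 3,
                                        seed = s))
    ranked <- choose_control_gene(qs$plate)
    grepl("^(AG|CTRL)", ranked$gene_id[1])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("amplification efficiency comes from the standard-curve slope", {
  res <- efficiency_from_dilution(c(100, 10, 1, 0.1),
                                  20 - 3.3219 * (log10(c(100, 10, 1, 0.1)) -
                                                   log10(100)))
  expect_equal(res$efficiency, 1.0, tolerance = 1e-4)
  res2 <- efficiency_from_dilution(c(100, 10, 1, 0.1),
                                   c(20, 23.6, 27.2, 30.8))
  expect_equal(res2$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-10)
  expect_equal(res2$slope, -3.6, tolerance = 1e-10)
  expect_error(efficiency_from_dilution(c(100, 10, 1), c(22, 21, 20)),
               "slope")
  expect_error(efficiency_from_dilution(c(10, 9, 8), c(25, 25.1, 25.2)),
               "2 log10")
})

test_that("Fisher synteny test matches brute-force hypergeometric enumeration", {
  res <- synteny_disruption_test(1, 21, 15, 745)
  expect_gte(res$p_one_sided, 0.35)
  expect_lte(res$p_one_sided, 0.38)
  expect_equal(res$p_one_sided, hypergeom_p_greater(1, 21, 15, 745),
               tolerance = 1e-12)

  expect_equal(synteny_disruption_test(0, 21, 0, 745)$p_one_sided, 1)
  expect_lt(synteny_disruption_test(21, 21, 0, 745)$p_one_sided, 1e-6)
  expect_error(synteny_disruption_test(-1, 21, 15, 745), "non-negative")
  expect_error(synteny_disruption_test(22, 21, 15, 745), "exceeds")

  # random small tables agree with the oracle
  set.seed(19)
  for (i in 1:50) {
    ot <- sample(2:40, 1); bt <- sample(2:900, 1)
    om <- sample(0:ot, 1); bm <- sample(0:bt, 1)
    expect_lt(abs(synteny_disruption_test(om, ot, bm, bt)$p_one_sided -
                    hypergeom_p_greater(om, ot, bm, bt)), 1e-12)
  }
})

test_that("intron-length consistency regression behaves across regimes", {
  x <- c(250, 400, 700, 950, 1300, 1800, 2400)
  perfect <- intron_length_check(x, x)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 1)

  set.seed(20)
  noisy <- intron_length_check(x + rnorm(7, sd = 50), x)
  expect_gt(noisy$r_squared, 0.9)
  expect_equal(noisy$slope, 1, tolerance = 0.15)
  expect_lt(noisy$p_value, 0.001)

  rand <- intron_length_check(rnorm(20, 1000, 10), seq(200, 2100, 100))
  expect_lt(rand$r_squared, 0.3)
  expect_error(intron_length_check(c(1, 2), c(1, 2)), "3 paired")
})

test_that("end-to-end qPCR simulation recovers every truth label in most seeds", {
  ok <- vapply(1:40, function(s) {
    qs <- simulate_qpcr(qpcr_sim_config(seed = s))
    lt <- locus_mf_tests(plate_concentrations(qs$plate,
                                              qs$config$control_gene_id))
    calls <- call_z_linkage_all(lt)
    truth <- ifelse(grepl("^ZG", calls$gene_id), "Z_linked", "autosomal")
    all(calls$call == truth)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("plate CSVs round-trip", {
  qs <- simulate_qpcr(qpcr_sim_config(n_z_genes = 3, n_autosomal_genes = 1,
                                      seed = 33))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(qs$plate, path, row.names = FALSE, quote = FALSE)
  back <- read_qpcr_plate(path)
  expect_equal(back$ct1, qs$plate$ct1, tolerance = 1e-12)
  expect_identical(back$gene_id, qs$plate$gene_id)
  expect_error(read_qpcr_plate(file.path(tempdir(), "missing_plate.csv")),
               "not found")
})
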
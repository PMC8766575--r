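jx_fixture <- function(bsj, linear, samples = NULL) {
  n <- length(bsj)
  data.table::data.table(
    gene_id = sprintf("G%02d", seq_len(n)),
    sample_id = samples %||% rep("s1", n),
    backsplice_reads = as.integer(bsj),
    linear_junction_reads = as.integer(linear))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("global circ level is back-splice reads per million", {
  jx <- jx_fixture(c(1500, 500), c(100, 100))
  out <- global_circ_level(jx, c(s1 = 4e7))
  expect_equal(out$bsj_per_million, 50)
  out0 <- global_circ_level(jx_fixture(0, 10), c(s1 = 4e7))
  expect_equal(out0$bsj_per_million, 0)
  expect_error(global_circ_level(jx, c(s1 = 0)), "positive")
  expect_error(global_circ_level(jx, c(other = 1e6)), "no mapped-read total")
})

test_that("Fisher exact p matches the hypergeometric enumeration oracle", {
  tabs <- list(c(8, 2, 1, 9), c(5, 5, 5, 5), c(3, 0, 0, 3), c(1, 7, 4, 2),
               c(12, 3, 9, 8), c(0, 10, 2, 8))
  for (tb in tabs) {
    p_pkg <- stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                                conf.int = FALSE)$p.value
    p_ora <- oracle_fisher_p(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p_pkg, p_ora, tolerance = 1e-10)
  }
})

test_that("Alu association reports group proportions and Fisher p", {
  flags <- data.table::data.table(
    gene_id = sprintf("G%02d", 1:20),
    has_circ_signature = rep(c(TRUE, FALSE), each = 10),
    overlaps_alu = c(rep(TRUE, 8), rep(FALSE, 2),
                     rep(TRUE, 1), rep(FALSE, 9)))
  res <- alu_association_test(flags)
  expect_equal(res$prop_circ, 0.8)
  expect_equal(res$prop_noncirc, 0.1)
  expect_equal(res$p_value, oracle_fisher_p(8, 2, 1, 9), tolerance = 1e-10)
  # balanced table -> p = 1
  flags2 <- data.table::copy(flags)
  flags2[, overlaps_alu := rep(c(rep(TRUE, 5), rep(FALSE, 5)), 2)]
  expect_equal(alu_association_test(flags2)$p_value, 1)
  # perfect separation by construction
  flags3 <- data.table::copy(flags)
  flags3[, overlaps_alu := has_circ_signature]
  res3 <- alu_association_test(flags3)
  expect_equal(res3$prop_circ, 1.0)
  expect_equal(res3$prop_noncirc, 0.0)
  # degenerate margins warn and return p = 1
  flags4 <- data.table::copy(flags)
  flags4[, overlaps_alu := TRUE]
  expect_warning(res4 <- alu_association_test(flags4), "degenerate")
  expect_equal(res4$p_value, 1)
})

test_that("circ gene flags derive from junction reads and Alu overlap", {
  genes <- data.table::data.table(gene_id = c("G01", "G02"), chrom = "chrS",
                                  start = c(1L, 1000L), end = c(500L, 1500L),
                                  strand = "+")
  reps <- data.table::data.table(chrom = "chrS", start = 100L, end = 150L,
                                 name = "AluSz", strand = "+")
  jx <- jx_fixture(c(3, 0), c(10, 10))
  fl <- circ_gene_flags(jx, genes, reps)
  expect_equal(fl[gene_id == "G01", has_circ_signature], TRUE)
  expect_equal(fl[gene_id == "G02", has_circ_signature], FALSE)
  expect_equal(fl[gene_id == "G01", overlaps_alu], TRUE)
  expect_equal(fl[gene_id == "G02", overlaps_alu], FALSE)
})

diff_circ_sheet <- function(n_pat = 6L, pathology = "A2") {
  pats <- sprintf("P%d", seq_len(n_pat))
  data.table::data.table(
    sample_id = c(paste0(pats, "T"), paste0(pats, "N")),
    patient_id = rep(pats, 2),
    condition = rep(c("tumor", "normal"), each = n_pat),
    pathology = pathology)
}

test_that("the back-splice gate is strictly more than min_bsj", {
  sheet <- diff_circ_sheet(4L)
  # gene G01 peaks at exactly 3 BSJ -> never tested; G02 reaches 4 -> tested
  jx <- data.table::rbindlist(lapply(sheet$sample_id, function(s)
    data.table::data.table(gene_id = c("G01", "G02"), sample_id = s,
                           backsplice_reads = c(3L, 4L),
                           linear_junction_reads = c(7L, 6L))))
  res <- diff_circ_rate(jx, sheet, "A2")
  expect_false("G01" %in% res$unit_id)
  expect_true("G02" %in% res$unit_id)
  # rate arithmetic: 3 of (3 + 7) = 0.3
  expect_equal(jx[gene_id == "G01",
                  unique(backsplice_reads /
                           (backsplice_reads + linear_junction_reads))], 0.3)
  # empty gate result
  jx0 <- data.table::copy(jx)[, backsplice_reads := 0L]
  expect_equal(nrow(diff_circ_rate(jx0, sheet, "A2")), 0L)
})

test_that("planted circ-rate shifts are recovered by the regression", {
  set.seed(55)
  sheet <- diff_circ_sheet(8L)
  genes <- sprintf("G%02d", 1:40)
  jx <- data.table::CJ(gene_id = genes, sample_id = sheet$sample_id)
  jx <- merge(jx, sheet, by = "sample_id")
  jx[, depth := stats::rpois(.N, 200)]
  jx[, rate := 0.20 - 0.05 * (condition == "tumor" &
                                gene_id <= "G20")]
  jx[, backsplice_reads := stats::rbinom(.N, depth, rate)]
  jx[, linear_junction_reads := depth - backsplice_reads]
  res <- diff_circ_rate(jx[, .(gene_id, sample_id, backsplice_reads,
                               linear_junction_reads)], sheet, "A2")
  shifted <- res[unit_id <= "G20"]
  expect_lt(abs(mean(shifted$diff) - (-0.05)), 0.02)
  nulls <- res[unit_id > "G20"]
  expect_lte(mean(nulls$fdr_adjusted_p < 0.05), 0.10)
  expect_gte(mean(shifted$fdr_adjusted_p < 0.05), 0.5)
})

test_that("gene-set overlap uses the expressed universe and errors outside it", {
  uni <- sprintf("G%03d", 1:100)
  res0 <- overlap_diff_genes(uni[1:10], uni[11:20], uni)
  expect_equal(length(res0$intersection), 0L)
  res10 <- overlap_diff_genes(uni[1:10], uni[1:10], uni)
  expect_equal(length(res10$intersection), 10L)
  expect_equal(res10$p_value, oracle_fisher_p(10, 0, 0, 90), tolerance = 1e-10)
  expect_error(overlap_diff_genes(c(uni[1:5], "GX"), uni[1:5], uni),
               "absent from the universe")
  expect_error(overlap_diff_genes(uni[1], uni[2], character()), "empty")
})

test_that("flanking-intron co-localization tracks circRNA boundaries", {
  genes <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  start = 1L, end = 1000L, strand = "+")
  exons <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  start = c(1L, 401L, 801L),
                                  end = c(200L, 600L, 1000L))
  circs <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  circ_start = 401L, circ_end = 600L)
  # site in the upstream flanking intron (201..400)
  s_up <- data.table::data.table(chrom = "chrS", pos = 300L, gene_id = "G01")
  # site in the downstream flanking intron (601..800)
  s_dn <- data.table::data.table(chrom = "chrS", pos = 700L, gene_id = "G01")
  # site in an exon: not in any flanking intron
  s_ex <- data.table::data.table(chrom = "chrS", pos = 100L, gene_id = "G01")
  expect_true(flanking_intron_colocalization(s_up, circs, genes,
                                             exons)$per_gene$colocalized)
  expect_true(flanking_intron_colocalization(s_dn, circs, genes,
                                             exons)$per_gene$colocalized)
  expect_false(flanking_intron_colocalization(s_ex, circs, genes,
                                              exons)$per_gene$colocalized)
  expect_equal(flanking_intron_colocalization(
    rbind(s_up, s_ex), circs, genes, exons)$fraction, 1.0)
  # circRNA outside the gene body warns and is skipped
  bad <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                circ_start = 1200L, circ_end = 1400L)
  expect_warning(res <- flanking_intron_colocalization(s_up, bad, genes,
                                                       exons),
                 "outside gene body")
  expect_false(res$per_gene$colocalized)
})

test_that("a distal intron does not count as flanking", {
  genes <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  start = 1L, end = 1400L, strand = "+")
  exons <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  start = c(1L, 401L, 801L, 1201L),
                                  end = c(200L, 600L, 1000L, 1400L))
  circs <- data.table::data.table(gene_id = "G01", chrom = "chrS",
                                  circ_start = 401L, circ_end = 600L)
  s_distal <- data.table::data.table(chrom = "chrS", pos = 1100L,
                                     gene_id = "G01")  # intron 3
  expect_false(flanking_intron_colocalization(s_distal, circs, genes,
                                              exons)$per_gene$colocalized)
})

test_that("KS comparison of editing deltas behaves at its contracts", {
  x <- stats::rnorm(100)
  res_same <- delta_cdf_comparison(c(x, x), rep(c(TRUE, FALSE), each = 100))
  expect_equal(res_same$statistic, 0)
  expect_equal(res_same$p_value, 1)
  set.seed(2)
  y <- c(stats::rnorm(500), stats::rnorm(500, 0.5))
  res_shift <- delta_cdf_comparison(y, rep(c(TRUE, FALSE), each = 500))
  expect_lt(res_shift$p_value, 1e-6)
  expect_error(delta_cdf_comparison(x, rep(TRUE, 100)), "at least two")
})
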
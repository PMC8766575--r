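test_that("positional filter is strict 'more than half'", {
  expect_false(positional_filter(4L, 3L))   # 3 > 2 -> fail
  expect_true(positional_filter(4L, 2L))    # 2 is not > 2 -> pass
  expect_true(positional_filter(1L, 0L))    # interior mismatch passes
  expect_false(positional_filter(1L, 1L))
})

test_that("major-allele rule needs >= 5 reads and a strict 2x margin", {
  expect_true(major_allele_filter(c(G = 6L, T = 2L))$pass)    # 6 >= 5, 6 > 4
  expect_equal(major_allele_filter(c(G = 6L, T = 2L))$major, "G")
  expect_false(major_allele_filter(c(G = 6L, T = 3L))$pass)   # 6 is not > 6
  expect_false(major_allele_filter(c(G = 4L, T = 1L))$pass)   # 4 < 5
  # the rule applies only with multiple alternative alleles
  expect_true(major_allele_filter(c(G = 2L))$pass)
})

test_that("variant class is expressed on the transcribed strand", {
  expect_equal(classify_variant("T", "C", "-"), "A>G")
  expect_equal(classify_variant("A", "G", "+"), "A>G")
  expect_equal(classify_variant("G", "A", "-"), "C>T")
  expect_equal(classify_variant("C", "T", "+"), "C>T")
  # all 12 classes are reachable and unique
  combos <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$r != combos$a, ]
  expect_equal(sort(unique(classify_variant(combos$r, combos$a, "+"))),
               sort(unique(classify_variant(combos$r, combos$a, "-"))))
  expect_equal(length(unique(classify_variant(combos$r, combos$a, "+"))), 12L)
})

test_that("call_site honors the >= 3 alternate-read threshold", {
  p3 <- pileup_fixture(n_alt = 3L)
  p2 <- pileup_fixture(n_alt = 2L)
  c3 <- call_editing_sites(p3$pileup)
  c2 <- call_editing_sites(p2$pileup)
  expect_equal(nrow(c3), 1L)
  expect_equal(c3$class, "A>G")
  expect_equal(c3$alt_reads, 3L)
  expect_equal(c3$level, 3 / 13)
  expect_equal(nrow(c2), 0L)
})

test_that("common SNPs are excluded unless flagged cDNA-derived", {
  p <- pileup_fixture(n_alt = 9L)
  snp <- data.table::data.table(chrom = "chrS", pos = 11L, cdna = FALSE)
  snp_cdna <- data.table::data.table(chrom = "chrS", pos = 11L, cdna = TRUE)
  expect_equal(nrow(call_editing_sites(p$pileup, snp)), 0L)
  expect_equal(nrow(call_editing_sites(p$pileup, snp_cdna)), 1L)
  # a catalog entry elsewhere does not interfere
  other <- data.table::data.table(chrom = "chrS", pos = 99L, cdna = FALSE)
  expect_equal(nrow(call_editing_sites(p$pileup, other)), 1L)
})

test_that("multi-allele sites resolve through the major-allele rule", {
  pass <- pileup_fixture(n_alt = 6L, n_alt2 = 2L)       # 6 > 4 -> G major
  fail <- pileup_fixture(n_alt = 6L, n_alt2 = 3L)       # 6 not > 6
  cp <- call_editing_sites(pass$pileup)
  expect_equal(cp$alt, "G")
  expect_equal(cp$alt_reads, 6L)
  expect_equal(nrow(call_editing_sites(fail$pileup)), 0L)
})

test_that("strand votes of mate 1 and mate 2 combine to the transcribed strand", {
  ref <- c(chrS = strrep("ACGTT", 10))
  mk <- function(mate, strand, i) {
    s <- substr(ref[[1]], 1, 40)
    substr(s, 11, 11) <- "G"
    make_read(s, mate = mate, strand = strand, read_id = paste0("m", i))
  }
  # mate 2 on +, mate 1 on -: both vote "+" under the reverse protocol
  reads <- rbind(mk(2L, "+", 1), mk(1L, "-", 2), mk(2L, "+", 3))
  calls <- call_editing_sites(build_pileup(expand_aligned_bases(reads), ref))
  expect_equal(calls$tx_strand, "+")
  expect_equal(calls$class, "A>G")
  # opposite configuration: transcribed strand -, genomic A>G reads as T>C
  reads2 <- rbind(mk(2L, "-", 1), mk(1L, "+", 2), mk(2L, "-", 3))
  calls2 <- call_editing_sites(build_pileup(expand_aligned_bases(reads2), ref))
  expect_equal(calls2$tx_strand, "-")
  expect_equal(calls2$class, "T>C")
  # exact tie -> dropped
  reads3 <- rbind(mk(2L, "+", 1), mk(2L, "-", 2), mk(2L, "+", 3),
                  mk(2L, "-", 4))
  calls3 <- call_editing_sites(build_pileup(expand_aligned_bases(reads3), ref))
  expect_equal(nrow(calls3), 0L)
})

make_call <- function(sample_id, pos, class = "A>G", strand = "+") {
  data.table::data.table(sample_id = sample_id, chrom = "chrS", pos = pos,
                         tx_strand = strand, class = class, ref = "A",
                         alt = "G", ref_reads = 10L, alt_reads = 5L,
                         level = 1 / 3)
}

sheet4 <- data.table::data.table(
  sample_id = c("P1T", "P1N", "P2T", "P2N", "P3T", "P3N"),
  patient_id = rep(c("P1", "P2", "P3"), each = 2),
  condition = rep(c("tumor", "normal"), 3),
  pathology = "O2")

test_that("consolidation keeps consistent sites seen in >= 2 patients", {
  calls <- rbind(make_call("P1T", 100L), make_call("P2N", 100L),  # 2 patients
                 make_call("P1T", 200L), make_call("P2T", 200L, class = "C>T"),
                 make_call("P3T", 300L), make_call("P3N", 300L))  # 1 patient
  cons <- consolidate_sites(calls, sheet4)
  expect_equal(cons$sites$pos, 100L)
  expect_equal(cons$sites$n_patients, 2L)
  # strand inconsistency also removes a site
  calls2 <- rbind(make_call("P1T", 100L, strand = "+"),
                  make_call("P2T", 100L, strand = "-"))
  expect_equal(nrow(consolidate_sites(calls2, sheet4)$sites), 0L)
  # unknown sample errors
  expect_error(consolidate_sites(make_call("PXT", 1L), sheet4),
               "missing from the sample sheet")
})

test_that("consolidation is idempotent", {
  calls <- rbind(make_call("P1T", 100L), make_call("P2N", 100L),
                 make_call("P2T", 150L), make_call("P3N", 150L))
  c1 <- consolidate_sites(calls, sheet4)
  c2 <- consolidate_sites(c1$calls[, -"patient_id"], sheet4)
  expect_equal(c1$sites, c2$sites)
})

test_that("annotation flags Alu and intronic context", {
  genes <- data.table::data.table(gene_id = "G1", chrom = "chrS",
                                  start = 1L, end = 1000L, strand = "+")
  exons <- data.table::data.table(gene_id = "G1", chrom = "chrS",
                                  start = c(1L, 801L), end = c(200L, 1000L),
                                  exon_number = 1:2)
  reps <- data.table::data.table(chrom = "chrS", start = 300L, end = 500L,
                                 name = "AluSx", strand = "+")
  sites <- data.table::data.table(chrom = "chrS",
                                  pos = c(400L, 100L, 600L, 1500L))
  ann <- annotate_sites(sites, reps, genes, exons)
  expect_equal(ann$in_alu, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ann$in_intron, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ann$gene_id, c("G1", "G1", "G1", NA))
  # a non-Alu repeat does not set the flag
  reps2 <- data.table::data.table(chrom = "chrS", start = 300L, end = 500L,
                                  name = "L1PA2", strand = "+")
  expect_false(annotate_sites(sites[1], reps2, genes, exons)$in_alu)
})

test_that("sites per million is simple depth normalization", {
  expect_equal(sites_per_million(500L, 5e7), 10)
  expect_equal(sites_per_million(0L, 5e7), 0)
  expect_error(sites_per_million(10L, 0), "positive")
  calls <- rbind(make_call("P1T", 1L), make_call("P1T", 2L, class = "C>T"))
  expect_equal(sites_per_million(calls, 1e6), 1)
})

test_that("caller output matches the naive oracle on a full sample", {
  co <- tiny_cohort()
  ref <- co$truth$genome$seq
  snps <- co$truth$snps[, .(chrom, pos, cdna)]
  smp <- co$samples$sample_id[2]
  reads <- co$reads[sample_id == smp]
  v <- evaluate_reads(reads)
  pu <- build_pileup(expand_aligned_bases(reads[v$kept]), ref)
  calls <- call_editing_sites(pu, snps, smp)
  ora <- oracle_call_sample(reads, ref, snps)
  expect_equal(nrow(calls), nrow(ora))
  expect_equal(calls$pos, ora$pos)
  expect_equal(calls$class, ora$class)
  expect_equal(calls$alt_reads, ora$alt_reads)
  expect_equal(calls$ref_reads, ora$ref_reads)
  expect_equal(calls$level, ora$level)
})
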
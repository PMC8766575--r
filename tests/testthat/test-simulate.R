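test_that("genome layout honors the requested gene and repeat structure", {
  cfg <- simulation_config(seed = 3, pathology_sizes = c(O2 = 2L),
                           n_genes = 2L, n_alu_per_gene = 1L,
                           n_editing_sites = 10L, n_snps = 0L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 2L)
  expect_equal(nrow(g$repeats), 2L)
  expect_gt(nchar(g$seq[[1]]), 0L)
  expect_equal(nrow(g$exons), 6L)           # 3 exons per gene
  # every gene has >= 1 intron: exons leave gaps inside the gene body
  spans <- g$exons[, .(exonic = sum(end - start + 1L)), by = gene_id]
  bodies <- g$genes[, .(gene_id, body = end - start + 1L)]
  expect_true(all(merge(spans, bodies, by = "gene_id")[, exonic < body]))
  # repeats are named by Alu subfamily and sit inside introns
  expect_true(all(startsWith(g$repeats$name, "Alu")))
  # some repeat intervals contain homopolymer runs of >= 4
  runs <- vapply(seq_len(nrow(g$repeats)), function(i)
    homopolymer_content(substring(g$seq[[1]], g$repeats$start[i],
                                  g$repeats$end[i])), integer(1))
  expect_true(any(runs >= 4L))
})

test_that("identical seeds give byte-identical artifacts", {
  cfg <- simulation_config(seed = 7, pathology_sizes = c(O2 = 2L),
                           n_genes = 3L, n_editing_sites = 20L, n_snps = 5L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth$genome$seq, c2$truth$genome$seq)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$junctions, c2$junctions)
  expect_identical(c1$truth$sites, c2$truth$sites)
})

test_that("no Alu request yields an empty repeat annotation", {
  cfg <- simulation_config(seed = 5, pathology_sizes = c(O2 = 2L),
                           n_genes = 2L, n_alu_per_gene = 0L,
                           n_editing_sites = 0L, n_snps = 0L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$repeats), 0L)
})

test_that("infeasible feature requests are rejected", {
  expect_error(simulation_config(seed = 1, pathology_sizes = c(O2 = 2L),
                                 n_genes = 1L, n_alu_per_gene = 1L,
                                 n_editing_sites = 500L),
               "too many editing sites")
  expect_error(simulation_config(seed = 1, pathology_sizes = c(O2 = 2L),
                                 intron_length = 100L),
               "too small")
  expect_error(simulation_config(seed = 1, pathology_sizes = c(O2 = 2L),
                                 base_error_rate = 1.5), "\\[0, 1\\]")
})

test_that("zero duplicate fraction leaves no duplicate-flagged read", {
  cfg <- simulation_config(seed = 9, pathology_sizes = c(O2 = 1L),
                           n_genes = 2L, n_editing_sites = 10L, n_snps = 0L,
                           frac_duplicates = 0)
  co <- simulate_cohort(cfg)
  expect_false(any(co$reads$dup))
})

test_that("level 1 with zero error makes every read carry the alternate", {
  cfg <- simulation_config(seed = 13, pathology_sizes = c(O2 = 1L),
                           n_genes = 2L, n_editing_sites = 5L, n_snps = 0L,
                           base_error_rate = 0, frac_low_qual = 0,
                           site_dispersion = 0,
                           level_range = c(1 - 1e-12, 1),
                           editing_delta_tumor = c(O2 = 0))
  co <- simulate_cohort(cfg)
  reads <- co$reads[sample_id == "P01N"]
  reads <- reads[evaluate_reads(reads)$kept]
  bases <- expand_aligned_bases(reads)
  for (i in seq_len(nrow(co$truth$sites))) {
    at <- bases[gpos == co$truth$sites$pos[i]]
    expect_true(all(at$base == co$truth$sites$alt[i]))
  }
})

test_that("observed alternate fraction concentrates on the planted level", {
  # high coverage, vanishing dispersion: binomial concentration within 0.02
  cfg <- simulation_config(seed = 17, pathology_sizes = c(O2 = 1L),
                           n_genes = 1L, n_alu_per_gene = 2L,
                           n_editing_sites = 4L, n_snps = 0L,
                           base_error_rate = 0, frac_low_qual = 0,
                           frac_duplicates = 0, frac_multimap = 0,
                           frac_clipped = 0, frac_indel = 0,
                           frac_homopolymer_reads = 0,
                           coverage_mean = 3000, site_dispersion = 0,
                           level_range = c(0.3 - 1e-12, 0.3),
                           editing_delta_tumor = c(O2 = 0))
  co <- simulate_cohort(cfg)
  reads <- co$reads[sample_id == "P01N"]
  for (i in seq_len(nrow(co$truth$sites))) {
    p <- co$truth$sites$pos[i]
    cov <- reads[pos <= p & p <= pos + cfg$read_length - 1L]
    b <- substring(cov$seq, p - cov$pos + 1L, p - cov$pos + 1L)
    frac <- mean(b == co$truth$sites$alt[i])
    expect_lt(abs(frac - 0.3), 0.02)
  }
})

test_that("SNPs are planted at DNA-like fractions disjoint from editing sites", {
  co <- tiny_cohort()
  expect_equal(length(intersect(co$truth$snps$pos, co$truth$sites$pos)), 0L)
  expect_true(all(co$truth$snp_zygosity$frac %in% c(0.5, 1.0)))
  # every planted site appears exactly once
  expect_equal(anyDuplicated(co$truth$sites$pos), 0L)
})

test_that("junction counts follow the configured rates and shifts", {
  # zero rate -> all back-splice counts zero
  cfg0 <- simulation_config(seed = 21, pathology_sizes = c(O2 = 2L),
                            n_genes = 3L, n_editing_sites = 5L,
                            circ_rate_normal = 0,
                            circ_delta_tumor = c(O2 = 0))
  co0 <- simulate_cohort(cfg0, alignments = FALSE)
  expect_true(all(co0$junctions$backsplice_reads == 0L))

  # mean back-splice fraction tracks the rate
  cfg1 <- simulation_config(seed = 22, pathology_sizes = c(GBM = 5L),
                            n_genes = 20L, n_editing_sites = 5L,
                            circ_rate_normal = 0.3, circ_dispersion = 0,
                            junction_depth_mean = 200,
                            circ_delta_tumor = c(GBM = 0))
  co1 <- simulate_cohort(cfg1, alignments = FALSE)
  jx <- co1$junctions
  jx[, tot := backsplice_reads + linear_junction_reads]
  expect_lt(abs(sum(jx$backsplice_reads) / sum(jx$tot) - 0.3), 0.01)

  # a -0.2 tumor shift appears in the mean rate difference across patients
  cfg2 <- simulation_config(seed = 23, pathology_sizes = c(GBM = 20L),
                            n_genes = 10L, n_editing_sites = 5L,
                            circ_rate_normal = 0.5, circ_dispersion = 0.01,
                            junction_depth_mean = 300,
                            circ_delta_tumor = c(GBM = -0.2))
  co2 <- simulate_cohort(cfg2, alignments = FALSE)
  jx2 <- merge(co2$junctions, co2$samples, by = "sample_id")
  jx2[, rate := backsplice_reads / (backsplice_reads + linear_junction_reads)]
  dd <- jx2[, .(m = mean(rate)), by = condition]
  expect_lt(abs((dd[condition == "tumor", m] - dd[condition == "normal", m]) -
                  (-0.2)), 0.02)
})

test_that("simulated artifact fractions materialize in the read table", {
  co <- tiny_cohort()
  v <- evaluate_reads(co$reads[sample_id == co$samples$sample_id[1]])
  # all five artifact classes occur at the configured (nonzero) fractions
  expect_gt(sum(v$duplicate), 0L)
  expect_gt(sum(v$multimapped), 0L)
  expect_gt(sum(v$clipped), 0L)
  expect_gt(sum(v$homopolymer), 0L)
  expect_gt(sum(v$indel), 0L)
})
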
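#' Simulation configuration for a synthetic paired tumor-normal cohort
#'
#' Builds and validates the full parameter set that drives the synthetic-data
#' generator.  The defaults describe a glioma-style study design: 41 patients,
#' each contributing one tumor and one matched neurotypical (normal) sample,
#' split across six pathology groups (oligodendroglioma grades 2-3, IDH-mutant
#' astrocytoma grades 2-4, glioblastoma), with A-to-I editing sites planted in
#' intronic Alu elements, germline SNPs, read-level artifacts (PCR duplicates,
#' multi-mappers, clipped/homopolymer/indel reads) and per-gene back-splice
#' junction counts whose rates shift in tumors.
#'
#' @param seed integer seed; the same seed yields byte-identical artifacts.
#' @param pathology_sizes named integer vector of patients per pathology.
#'   The default mirrors the cohort design: O2=6, O3=9, A2=4, A3=5, A4=2,
#'   GBM=15 (41 patients in total).
#' @param n_genes number of genes laid out on the synthetic contig.
#' @param n_alu_per_gene Alu intervals planted per gene (in introns).
#' @param n_editing_sites total A-to-I sites planted (in Alu introns).
#' @param editing_level_shape Beta(a, b) hyper-parameters for per-site
#'   baseline editing levels in normal tissue.
#' @param level_range baseline levels are clamped into this interval.
#' @param editing_delta_tumor named per-pathology additive shift applied to
#'   editing levels in tumor samples (clamped to \[0, 1\]).
#' @param site_dispersion intraclass correlation of the per-sample
#'   beta-binomial read-level draw at each site, in \[0, 1).
#' @param coverage_mean target mean read depth per site.
#' @param read_length read length in nt.
#' @param fragment_length insert size of the simulated fragments.
#' @param frac_duplicates,frac_multimap,frac_clipped,frac_indel,frac_homopolymer_reads
#'   probabilities of the corresponding read-level artifact.
#' @param frac_low_qual per-base probability of a low (Phred 11) base quality.
#' @param n_snps number of germline SNPs planted (het or hom per patient).
#' @param snp_het_frac probability a patient is heterozygous (vs homozygous
#'   alternate) at a planted SNP.
#' @param frac_snp_cdna fraction of catalog SNP records flagged as
#'   cDNA-template-derived (these are *not* excluded by the caller).
#' @param base_error_rate per-base sequencing error probability.
#' @param base_quality Phred quality assigned to ordinary bases.
#' @param circ_rate_normal back-splice rate (BSJ / all junction reads) in
#'   normal tissue.
#' @param circ_delta_tumor named per-pathology additive shift of the
#'   back-splice rate in tumors.
#' @param circ_dispersion intraclass correlation of per-sample junction draws.
#' @param junction_depth_mean Poisson mean of total junction reads per gene.
#' @param exon_length,intron_length,alu_length,intergenic_gap genome layout
#'   lengths in nt.
#' @param contig name of the synthetic contig.
#'
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              pathology_sizes = c(O2 = 6L, O3 = 9L, A2 = 4L,
                                                  A3 = 5L, A4 = 2L, GBM = 15L),
                              n_genes = 12L,
                              n_alu_per_gene = 2L,
                              n_editing_sites = 200L,
                              editing_level_shape = c(2, 6),
                              level_range = c(0.05, 0.95),
                              editing_delta_tumor = c(O2 = 0.04, O3 = -0.08,
                                                      A2 = -0.30, A3 = -0.19,
                                                      A4 = -0.12, GBM = -0.07),
                              site_dispersion = 0.02,
                              coverage_mean = 30,
                              read_length = 101L,
                              fragment_length = 250L,
                              frac_duplicates = 0.10,
                              frac_multimap = 0.05,
                              frac_clipped = 0.05,
                              frac_indel = 0.02,
                              frac_homopolymer_reads = 0.02,
                              frac_low_qual = 0.02,
                              n_snps = 50L,
                              snp_het_frac = 0.5,
                              frac_snp_cdna = 0,
                              base_error_rate = 0.001,
                              base_quality = 37L,
                              circ_rate_normal = 0.10,
                              circ_delta_tumor = c(O2 = -0.01, O3 = -0.02,
                                                   A2 = -0.04, A3 = -0.04,
                                                   A4 = -0.03, GBM = -0.03),
                              circ_dispersion = 0.05,
                              junction_depth_mean = 100,
                              exon_length = 300L,
                              intron_length = 700L,
                              alu_length = 300L,
                              intergenic_gap = 200L,
                              contig = "chrS") {
  cfg <- as.list(environment())
  cfg$pathology_sizes <- as.integer(pathology_sizes)
  names(cfg$pathology_sizes) <- names(pathology_sizes)
  cfg$n_patients <- sum(cfg$pathology_sizes)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c("site_dispersion", "frac_duplicates", "frac_multimap",
             "frac_clipped", "frac_indel", "frac_homopolymer_reads",
             "frac_low_qual", "snp_het_frac", "frac_snp_cdna",
             "base_error_rate", "circ_rate_normal", "circ_dispersion")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must lie in [0, 1], got %s", p, format(v)))
  }
  if (cfg$site_dispersion >= 1 || cfg$circ_dispersion >= 1)
    stop("dispersions must lie in [0, 1)")
  if (cfg$n_genes < 1) stop("'n_genes' must be >= 1")
  if (is.null(names(cfg$pathology_sizes)) ||
      any(!nzchar(names(cfg$pathology_sizes))))
    stop("'pathology_sizes' must be a named vector")
  for (nm in c("editing_delta_tumor", "circ_delta_tumor")) {
    miss <- setdiff(names(cfg$pathology_sizes), names(cfg[[nm]]))
    if (length(miss))
      stop(sprintf("'%s' lacks entries for: %s", nm,
                   paste(miss, collapse = ", ")))
  }
  if (any(cfg$pathology_sizes < 0)) stop("pathology sizes must be >= 0")
  if (cfg$read_length < 20L) stop("'read_length' must be >= 20")
  if (cfg$fragment_length < 2L * cfg$read_length)
    stop("'fragment_length' must be >= 2 * read_length")
  if (cfg$level_range[1] < 0 || cfg$level_range[2] > 1 ||
      cfg$level_range[1] >= cfg$level_range[2])
    stop("'level_range' must be an increasing interval inside [0, 1]")
  # capacity: all requested Alu intervals must fit inside introns
  if (cfg$n_alu_per_gene > 0 &&
      cfg$intron_length < cfg$alu_length + 20L)
    stop("'intron_length' too small to host an Alu interval")
  n_alu <- cfg$n_genes * cfg$n_alu_per_gene
  if (cfg$n_editing_sites > 0 && n_alu == 0)
    stop("cannot plant editing sites without Alu intervals")
  if (n_alu > 0 && cfg$n_editing_sites > n_alu * (cfg$alu_length %/% 3))
    stop("too many editing sites requested for the available Alu space")
  invisible(cfg)
}

#' Default thresholds of the editing/circRNA pipeline
#'
#' All defaults are the canonical values of the method: base quality strictly
#' greater than 20, at least 3 alternate reads, end-proximity window of 5 nt,
#' major-allele minimum of 5 reads at a ratio of more than 2x, sites kept
#' when seen in at least 2 patients, FDR threshold 0.05, and a strict
#' more-than-3 back-splice-read gate for circRNA testing.
#'
#' @param min_qual Phred threshold; bases count only if quality > min_qual.
#' @param min_alt_reads minimum alternate-allele reads for a call.
#' @param end_distance mismatches within this many nt of either read end
#'   (terminal base = 1) count as end-proximal.
#' @param major_allele_min,major_allele_ratio major-allele rule when several
#'   alternate alleles exist.
#' @param min_patients minimum distinct patients for a consolidated site.
#' @param min_patients_test pathologies with fewer patients are skipped by
#'   differential testing (overridable).
#' @param fdr FDR significance threshold.
#' @param min_bsj genes enter circRNA testing only if max back-splice count
#'   across the compared samples is strictly greater than this.
#' @param strandedness `"reverse"` (mate 2 on the transcribed strand) or
#'   `"forward"`.
#' @param multimap_rule how multi-mapped reads are recognized: `"either"`
#'   (occupancy tag > 1 or mapping quality below `unique_mapq`), `"tag"`,
#'   or `"mapq"`.
#' @param unique_mapq mapping quality assigned by the aligner to uniquely
#'   mapped reads (STAR convention: 255).
#' @param dedup_overlap if TRUE, overlapping mates of one fragment count a
#'   shared position once; default FALSE (each mate counted independently).
#' @param snp_cdna_key INFO flag key marking cDNA-template-derived SNP
#'   records, which are exempt from SNP exclusion.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_qual = 20L,
                            min_alt_reads = 3L,
                            end_distance = 5L,
                            major_allele_min = 5L,
                            major_allele_ratio = 2,
                            min_patients = 2L,
                            min_patients_test = 3L,
                            fdr = 0.05,
                            min_bsj = 3L,
                            strandedness = c("reverse", "forward"),
                            multimap_rule = c("either", "tag", "mapq"),
                            unique_mapq = 255L,
                            dedup_overlap = FALSE,
                            snp_cdna_key = "CDNA") {
  strandedness <- match.arg(strandedness)
  multimap_rule <- match.arg(multimap_rule)
  p <- list(min_qual = as.integer(min_qual),
            min_alt_reads = as.integer(min_alt_reads),
            end_distance = as.integer(end_distance),
            major_allele_min = as.integer(major_allele_min),
            major_allele_ratio = major_allele_ratio,
            min_patients = as.integer(min_patients),
            min_patients_test = as.integer(min_patients_test),
            fdr = fdr,
            min_bsj = as.integer(min_bsj),
            strandedness = strandedness,
            multimap_rule = multimap_rule,
            unique_mapq = as.integer(unique_mapq),
            dedup_overlap = isTRUE(dedup_overlap),
            snp_cdna_key = snp_cdna_key)
  structure(p, class = "pipeline_params")
}
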
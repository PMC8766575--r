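#' Simulate a reference genome with genes, introns and Alu repeats
#'
#' Lays out `n_genes` genes on one synthetic contig, each with three exons
#' and two introns, alternating transcribed strand.  Alu intervals (labelled
#' with Alu subfamily names) are planted inside introns; every other interval
#' carries a short homopolymer run so that reads crossing it exercise the
#' homopolymer read filter below its threshold.
#'
#' @param config a [simulation_config()] object.
#' @return a list of class `sim_genome` with elements `seq` (named character,
#'   one contig), `genes`, `exons`, `repeats` (data.tables, 1-based inclusive
#'   coordinates) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  exl <- config$exon_length; inl <- config$intron_length
  gene_len <- 3L * exl + 2L * inl

  per_intron_cap <- max(0L, (inl - 20L) %/% (config$alu_length + 10L))
  if (config$n_alu_per_gene > 2L * per_intron_cap)
    stop("requested Alu intervals do not fit in the gene introns")

  genes <- data.table::data.table(
    gene_id = sprintf("G%03d", seq_len(config$n_genes)),
    chrom = config$contig,
    start = (seq_len(config$n_genes) - 1L) * (gene_len + config$intergenic_gap) + 1L,
    strand = rep_len(c("+", "-"), config$n_genes))
  genes[, end := start + gene_len - 1L]

  exons <- genes[, {
    s <- start + c(0L, exl + inl, 2L * (exl + inl))
    list(exon_number = 1:3, start = s, end = s + exl - 1L)
  }, by = .(gene_id, chrom, strand)]

  glen <- genes$end[nrow(genes)] + config$intergenic_gap
  seq_chr <- paste(sample(BASES, glen, replace = TRUE), collapse = "")

  repeats <- data.table::data.table(gene_id = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    name = character(), strand = character(),
                                    has_homopolymer = logical())
  if (config$n_alu_per_gene > 0L) {
    subfam <- c("AluSx", "AluY", "AluJb", "AluSq2", "AluSz")
    reps <- genes[, {
      k <- seq_len(config$n_alu_per_gene)
      intr <- ((k - 1L) %% 2L) + 1L              # host intron (1 or 2)
      slot <- (k - 1L) %/% 2L                    # slot within the intron
      intron_start <- start + intr * exl + (intr - 1L) * inl
      a_start <- intron_start + 10L + slot * (config$alu_length + 10L)
      list(start = a_start, end = a_start + config$alu_length - 1L)
    }, by = .(gene_id, chrom, strand)]
    reps[, name := sample(subfam, .N, replace = TRUE)]
    reps[, has_homopolymer := (seq_len(.N) %% 2L) == 1L]
    repeats <- reps
    # plant a 6-nt homopolymer run near the interval start (offset 20..25)
    for (i in which(repeats$has_homopolymer)) {
      run_at <- repeats$start[i] + 20L
      substr(seq_chr, run_at, run_at + 5L) <- strrep("A", 6L)
    }
  }

  seq_named <- c(seq_chr); names(seq_named) <- config$contig
  structure(list(seq = seq_named, genes = genes, exons = exons,
                 repeats = repeats, config = config),
            class = "sim_genome")
}

#' Sample sheet for the simulated cohort
#'
#' Two samples per patient (tumor and normal), with pathologies assigned by
#' the configured per-pathology patient counts.
#'
#' @param config a [simulation_config()].
#' @return data.table with columns sample_id, patient_id, condition,
#'   pathology.
#' @export
simulate_sample_sheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pid <- sprintf("P%02d", seq_len(config$n_patients))
  pathology <- rep(names(config$pathology_sizes), config$pathology_sizes)
  data.table::data.table(
    sample_id = as.vector(rbind(paste0(pid, "T"), paste0(pid, "N"))),
    patient_id = rep(pid, each = 2L),
    condition = rep(c("tumor", "normal"), config$n_patients),
    pathology = rep(pathology, each = 2L))
}

#' Plant ground-truth editing sites, SNPs and circRNA rates
#'
#' Editing sites are placed at intronic positions inside Alu intervals; the
#' reference base at each site is forced to be adenosine on the transcribed
#' strand (genomic A on + genes, T on - genes).  Each site gets a baseline
#' level from the configured Beta hyper-prior (clamped to `level_range`);
#' tumor samples add the per-pathology shift, clamped to \[0, 1\].  Germline
#' SNPs are planted at DNA-like fractions (0.5 heterozygous, 1.0 homozygous
#' per patient) at positions disjoint from editing sites.  Per-gene true
#' back-splice rates shift by the per-pathology circ delta in tumors.
#'
#' @param genome a [simulate_genome()] result.
#' @return list of class `sim_truth` holding the genome (possibly with
#'   site reference bases rewritten), sample sheet and truth tables.
#' @export
simulate_truth <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  config <- genome$config
  set.seed(config$seed + 1L)
  samples <- simulate_sample_sheet(config)
  seq_chr <- genome$seq[[1L]]
  strand_of_gene <- stats::setNames(genome$genes$strand, genome$genes$gene_id)

  # -- editing sites ---------------------------------------------------------
  sites <- data.table::data.table(site_id = character(), chrom = character(),
                                  pos = integer(), gene_id = character(),
                                  tx_strand = character(), ref = character(),
                                  alt = character(), baseline = numeric())
  site_levels <- data.table::data.table(site_id = character(),
                                        sample_id = character(),
                                        true_level = numeric())
  if (config$n_editing_sites > 0L) {
    if (nrow(genome$repeats) == 0L)
      stop("cannot plant editing sites: no Alu intervals in the genome")
    off <- seq(41L, config$alu_length - 10L, by = 3L)
    cand <- genome$repeats[, .(gene_id, chrom, start, tx_strand = strand)]
    cand <- cand[rep(seq_len(.N), each = length(off))]
    cand[, pos := start + rep(off, length.out = .N) - 1L]
    cand[, start := NULL]
    if (nrow(cand) < config$n_editing_sites)
      stop("too many editing sites requested for the available Alu space")
    pick <- sort(sample.int(nrow(cand), config$n_editing_sites))
    sites <- cand[pick]
    sites[, site_id := sprintf("S%04d", seq_len(.N))]
    sites[, ref := ifelse(tx_strand == "+", "A", "T")]
    sites[, alt := ifelse(tx_strand == "+", "G", "C")]
    base_raw <- stats::rbeta(nrow(sites), config$editing_level_shape[1],
                             config$editing_level_shape[2])
    sites[, baseline := clamp(base_raw, config$level_range[1],
                              config$level_range[2])]
    # force reference base to transcribed-strand adenosine
    for (i in seq_len(nrow(sites)))
      substr(seq_chr, sites$pos[i], sites$pos[i]) <- sites$ref[i]

    delta <- config$editing_delta_tumor[samples$pathology]
    site_levels <- data.table::CJ(site_id = sites$site_id,
                                  sample_id = samples$sample_id,
                                  sorted = FALSE)
    site_levels <- merge(site_levels, sites[, .(site_id, baseline)],
                         by = "site_id", sort = FALSE)
    site_levels <- merge(site_levels,
                         samples[, .(sample_id, condition, pathology)],
                         by = "sample_id", sort = FALSE)
    site_levels[, true_level := clamp(
      baseline + ifelse(condition == "tumor",
                        config$editing_delta_tumor[pathology], 0))]
    site_levels <- site_levels[, .(site_id, sample_id, true_level)]
    data.table::setkey(site_levels, site_id, sample_id)
  }

  # -- SNPs ------------------------------------------------------------------
  snps <- data.table::data.table(snp_id = character(), chrom = character(),
                                 pos = integer(), ref = character(),
                                 alt = character(), cdna = logical())
  snp_zygosity <- data.table::data.table(snp_id = character(),
                                         patient_id = character(),
                                         frac = numeric())
  if (config$n_snps > 0L) {
    body_pos <- unlist(lapply(seq_len(nrow(genome$genes)), function(i)
      seq(genome$genes$start[i], genome$genes$end[i])))
    forbidden <- if (nrow(sites)) unique(c(sites$pos - 1L, sites$pos,
                                           sites$pos + 1L)) else integer()
    body_pos <- setdiff(body_pos, forbidden)
    pos <- sort(sample(body_pos, config$n_snps))
    ref <- vapply(pos, function(p) substr(seq_chr, p, p), character(1))
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    snps <- data.table::data.table(
      snp_id = sprintf("SNP%04d", seq_len(config$n_snps)),
      chrom = config$contig, pos = pos, ref = ref, alt = unname(alt),
      cdna = stats::runif(config$n_snps) < config$frac_snp_cdna)
    pats <- unique(samples$patient_id)
    snp_zygosity <- data.table::CJ(snp_id = snps$snp_id, patient_id = pats,
                                   sorted = FALSE)
    snp_zygosity[, frac := ifelse(stats::runif(.N) < config$snp_het_frac,
                                  0.5, 1.0)]
  }

  # -- circRNA truth ---------------------------------------------------------
  # exonic circRNA over the middle exon; flanking introns are introns 1 and 2
  circ <- merge(genome$exons[exon_number == 2L,
                             .(gene_id, circ_start = start, circ_end = end)],
                genome$genes[, .(gene_id, chrom)], by = "gene_id")
  data.table::setcolorder(circ, c("gene_id", "chrom", "circ_start", "circ_end"))
  cd <- config$circ_delta_tumor[samples$pathology]
  circ_rates <- data.table::CJ(gene_id = genome$genes$gene_id,
                               sample_id = samples$sample_id, sorted = FALSE)
  circ_rates <- merge(circ_rates, samples[, .(sample_id, condition, pathology)],
                      by = "sample_id", sort = FALSE)
  circ_rates[, true_rate := clamp(
    config$circ_rate_normal + ifelse(condition == "tumor",
                                     config$circ_delta_tumor[pathology], 0))]
  circ_rates <- circ_rates[, .(gene_id, sample_id, true_rate)]
  data.table::setkey(circ_rates, gene_id, sample_id)

  genome$seq[[1L]] <- seq_chr
  structure(list(genome = genome, config = config, samples = samples,
                 sites = sites, site_levels = site_levels,
                 snps = snps, snp_zygosity = snp_zygosity,
                 circ = circ, circ_rates = circ_rates),
            class = "sim_truth")
}
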
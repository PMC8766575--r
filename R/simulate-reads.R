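#' Simulate stranded paired-end alignments with planted signal and artifacts
#'
#' Fragments are tiled over each gene body (pre-mRNA, so introns are covered)
#' at the configured mean coverage.  The library follows the reverse-stranded
#' convention: mate 2 aligns to the transcribed strand, mate 1 to its
#' opposite.  At every planted editing site a per-sample success probability
#' is drawn from Beta(level, dispersion) and each covering read carries the
#' alternate base with that probability (a beta-binomial read count); SNP
#' positions carry the alternate at the patient's DNA fraction (0.5 or 1.0).
#' Sequencing errors and low-quality bases are sprinkled per base.  Read
#' artifacts are then planted at the configured fractions: PCR-duplicate
#' copies (duplicate flag set), multi-mapped pairs (mapping quality 3,
#' occupancy tag 3), soft-clipped reads (6 nt clipped), indel reads (1-nt
#' insertion) and reads whose sequence carries >10 nt of homopolymer runs.
#'
#' @param truth a [simulate_truth()] bundle.
#' @return data.table of alignment records, one row per mate, with columns
#'   sample_id, read_id, mate, chrom, pos (1-based leftmost aligned), strand,
#'   mapq, nh, dup, cigar, seq, qual.
#' @export
simulate_alignments <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  if (config$coverage_mean < 1) stop("'coverage_mean' must be >= 1")
  set.seed(config$seed + 2L)
  genome <- truth$genome
  seq_chr <- genome$seq[[1L]]
  rl <- config$read_length
  frag <- config$fragment_length
  qual_base <- strrep(intToUtf8(33L + config$base_quality), rl)
  qual_low <- as.raw(33L + 11L)

  out <- vector("list", nrow(truth$samples))
  for (si in seq_len(nrow(truth$samples))) {
    smp <- truth$samples$sample_id[si]
    pat <- truth$samples$patient_id[si]

    # fragment layout per gene
    gl <- genome$genes[, .(gene_id, start, end, strand)]
    frs <- gl[, {
      lambda <- (end - start + 1L) * config$coverage_mean / (2 * rl)
      nf <- stats::rpois(1L, lambda)
      fs <- if (nf > 0L && (end - frag + 1L) >= start)
        sample(seq.int(start, end - frag + 1L), nf, replace = TRUE)
      else integer()
      list(fstart = fs)
    }, by = .(gene_id, strand)]
    if (nrow(frs) == 0L) stop("no fragments simulated; increase coverage")
    nf <- nrow(frs)
    frs[, frag_id := sprintf("%s_f%06d", smp, seq_len(nf))]

    # two mates per fragment; mate 2 sits on the transcribed (gene) strand
    left <- frs[, .(gene_id, read_id = frag_id,
                    mate = ifelse(strand == "+", 2L, 1L),
                    pos = fstart, strand = "+")]
    right <- frs[, .(gene_id, read_id = frag_id,
                     mate = ifelse(strand == "+", 1L, 2L),
                     pos = fstart + frag - rl, strand = "-")]
    reads <- rbind(left, right)
    reads[, seq := substring(seq_chr, pos, pos + rl - 1L)]
    reads[, `:=`(cigar = paste0(rl, "M"), mapq = 255L, nh = 1L, dup = FALSE)]

    # ---- planted editing sites (beta-binomial per sample) -----------------
    if (nrow(truth$sites)) {
      lev <- truth$site_levels[.(truth$sites$site_id, smp), true_level]
      psite <- rbeta_mu_rho(nrow(truth$sites), lev, config$site_dispersion)
      reads <- plant_substitutions(reads, truth$sites$pos, truth$sites$alt,
                                   psite, rl)
    }
    # ---- germline SNPs -----------------------------------------------------
    if (nrow(truth$snps)) {
      frac <- truth$snp_zygosity[.(truth$snps$snp_id, pat), frac,
                                 on = c("snp_id", "patient_id")]
      reads <- plant_substitutions(reads, truth$snps$pos, truth$snps$alt,
                                   frac, rl)
    }
    # ---- sequencing errors -------------------------------------------------
    if (config$base_error_rate > 0) {
      n_err <- stats::rbinom(1L, nrow(reads) * rl, config$base_error_rate)
      if (n_err > 0L) {
        ridx <- sample.int(nrow(reads), n_err, replace = TRUE)
        off <- sample.int(rl, n_err, replace = TRUE)
        cur <- vapply(seq_len(n_err),
                      function(j) substr(reads$seq[ridx[j]], off[j], off[j]),
                      character(1))
        newb <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                       character(1))
        reads[, seq := substr_assign(seq, ridx, off, newb)]
      }
    }
    # ---- base qualities ----------------------------------------------------
    reads[, qual := qual_base]
    if (config$frac_low_qual > 0) {
      n_low <- stats::rbinom(1L, nrow(reads) * rl, config$frac_low_qual)
      if (n_low > 0L) {
        ridx <- sample.int(nrow(reads), n_low, replace = TRUE)
        off <- sample.int(rl, n_low, replace = TRUE)
        affected <- sort(unique(ridx))
        raw <- charToRaw(paste0(reads$qual[affected], collapse = ""))
        raw[(match(ridx, affected) - 1L) * rl + off] <- qual_low
        big <- rawToChar(raw)
        st <- (seq_along(affected) - 1L) * rl + 1L
        reads$qual[affected] <- substring(big, st, st + rl - 1L)
      }
    }
    # ---- read artifacts ----------------------------------------------------
    nr <- nrow(reads)
    # multi-mapped: whole fragments
    mm_frag <- frs$frag_id[stats::runif(nf) < config$frac_multimap]
    reads[read_id %in% mm_frag, `:=`(mapq = 3L, nh = 3L)]
    # soft-clipped: per read, first 6 nt re-labelled as clipped
    cl <- which(stats::runif(nr) < config$frac_clipped)
    if (length(cl)) {
      reads$cigar[cl] <- paste0("6S", rl - 6L, "M")
      reads$pos[cl] <- reads$pos[cl] + 6L
    }
    # indel: per read, 1-nt insertion after 50 aligned bases
    half <- 50L
    ind <- which(stats::runif(nr) < config$frac_indel)
    ind <- setdiff(ind, cl)
    if (length(ind)) {
      p <- reads$pos[ind]
      reads$seq[ind] <- paste0(substring(seq_chr, p, p + half - 1L), "A",
                               substring(seq_chr, p + half, p + rl - 2L))
      reads$cigar[ind] <- paste0(half, "M1I", rl - half - 1L, "M")
    }
    # homopolymer-rich: 5+7 nt runs (12 nt total, above the 10-nt limit)
    hp <- which(stats::runif(nr) < config$frac_homopolymer_reads)
    if (length(hp)) {
      for (i in hp) {
        substr(reads$seq[i], 41L, 45L) <- "AAAAA"
        substr(reads$seq[i], 46L, 52L) <- "GGGGGGG"
      }
    }
    # PCR duplicates: flagged copies of existing fragments
    dup_frag <- frs$frag_id[stats::runif(nf) < config$frac_duplicates]
    if (length(dup_frag)) {
      dups <- reads[read_id %in% dup_frag]
      dups[, `:=`(read_id = paste0(read_id, "d"), dup = TRUE)]
      reads <- rbind(reads, dups)
    }
    reads[, `:=`(sample_id = smp, chrom = config$contig)]
    out[[si]] <- reads
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("sample_id", "read_id", "mate", "chrom",
                                 "pos", "strand", "mapq", "nh", "dup",
                                 "cigar", "seq", "qual", "gene_id"))
  res[]
}

# Plant alternate bases at given genomic positions into covering reads.
# prob is per-position; covering reads are found on the simple all-M layout
# (this runs before clip/indel artifacts are introduced).
plant_substitutions <- function(reads, positions, alt, prob, rl) {
  keep <- prob > 0
  if (!any(keep)) return(reads)
  positions <- positions[keep]; alt <- alt[keep]; prob <- prob[keep]
  hits <- lapply(seq_along(positions), function(k) {
    rows <- which(reads$pos <= positions[k] & positions[k] <= reads$pos + rl - 1L)
    if (!length(rows)) return(NULL)
    rows <- rows[stats::runif(length(rows)) < prob[k]]
    if (!length(rows)) return(NULL)
    data.table::data.table(row = rows,
                           off = positions[k] - reads$pos[rows] + 1L,
                           base = alt[k])
  })
  hits <- data.table::rbindlist(hits)
  if (nrow(hits))
    reads[, seq := substr_assign(seq, hits$row, hits$off, hits$base)]
  reads
}

#' Simulate per-gene junction count tables
#'
#' For every gene and sample, the total junction depth is Poisson with the
#' configured mean, and the back-splice count is a beta-binomial draw of that
#' depth at the sample's true back-splice rate (tumor rates carry the
#' per-pathology shift, clamped to \[0, 1\]).
#'
#' @param truth a [simulate_truth()] bundle.
#' @return data.table with gene_id, sample_id, backsplice_reads,
#'   linear_junction_reads.
#' @export
simulate_junction_counts <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(config$seed + 3L)
  jx <- data.table::CJ(gene_id = truth$genome$genes$gene_id,
                       sample_id = truth$samples$sample_id, sorted = FALSE)
  jx <- merge(jx, truth$circ_rates, by = c("gene_id", "sample_id"),
              sort = FALSE)
  jx[, depth := stats::rpois(.N, config$junction_depth_mean)]
  jx[, backsplice_reads := rbetabinom(.N, depth, true_rate,
                                      config$circ_dispersion)]
  jx[, linear_junction_reads := depth - backsplice_reads]
  jx[, c("depth", "true_rate") := NULL]
  jx[]
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genome()], [simulate_truth()],
#' [simulate_alignments()] and [simulate_junction_counts()] in order.
#'
#' @param config a [simulation_config()].
#' @param alignments if FALSE, skip read simulation (junctions only).
#' @return list of class `sim_cohort` with the truth bundle, the read table
#'   and the junction table.
#' @export
simulate_cohort <- function(config, alignments = TRUE) {
  truth <- simulate_truth(simulate_genome(config))
  reads <- if (alignments) simulate_alignments(truth) else NULL
  junctions <- simulate_junction_counts(truth)
  structure(list(config = config, truth = truth, reads = reads,
                 junctions = junctions, samples = truth$samples),
            class = "sim_cohort")
}
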
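# Readers and writers for the standard interchange formats.  Internal
# coordinates are 1-based inclusive; conversion to 0-based half-open happens
# only at the BED boundary, and VCF/GTF stay 1-based.

#' Write the cohort's reference and annotation files
#'
#' Writes the reference FASTA, a GENCODE-dialect GTF (gene and exon
#' records), a BED6 repeat annotation (Alu subfamily in the name field,
#' 0-based half-open), a minimal VCF SNP catalog (cDNA-derived records
#' carry the configured INFO flag), the sample sheet, the junction table and
#' the truth tables as TSV.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param dir output directory (created if missing).
#' @param params a [pipeline_params()] (supplies the cDNA INFO key).
#' @param bam if TRUE also write per-sample coordinate-sorted BAM files.
#' @return named list of written paths (class `cohort_paths`), suitable as
#'   input to [run_pipeline()].
#' @export
write_cohort_files <- function(cohort, dir, params = pipeline_params(),
                               bam = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth
  genome <- truth$genome
  p <- list()

  p$ref_fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, p$ref_fasta)

  p$genes_gtf <- file.path(dir, "genes.gtf")
  write_gene_gtf(genome$genes, genome$exons, p$genes_gtf)

  p$repeats_bed <- file.path(dir, "repeats.bed")
  write_repeat_bed(genome$repeats, p$repeats_bed)

  p$snp_vcf <- file.path(dir, "snps.vcf")
  write_snp_vcf(truth$snps, p$snp_vcf, cdna_key = params$snp_cdna_key)

  p$sample_sheet <- file.path(dir, "samples.tsv")
  data.table::fwrite(truth$samples, p$sample_sheet, sep = "\t")

  p$junctions <- file.path(dir, "junctions.tsv")
  data.table::fwrite(cohort$junctions, p$junctions, sep = "\t")

  p$circ_coords <- file.path(dir, "circ_coords.tsv")
  data.table::fwrite(truth$circ, p$circ_coords, sep = "\t")

  p$truth_sites <- file.path(dir, "truth_sites.tsv")
  data.table::fwrite(truth$sites, p$truth_sites, sep = "\t")
  p$truth_levels <- file.path(dir, "truth_site_levels.tsv")
  data.table::fwrite(truth$site_levels, p$truth_levels, sep = "\t")

  if (bam && !is.null(cohort$reads)) {
    p$bams <- write_sample_bams(cohort$reads, genome, file.path(dir, "bam"))
  }
  structure(p, class = "cohort_paths")
}

write_gene_gtf <- function(genes, exons, path) {
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end),
                                 strand = genes$strand)
  S4Vectors::mcols(gr_g) <- S4Vectors::DataFrame(
    source = "aluedit_sim", type = "gene", gene_id = genes$gene_id,
    gene_name = genes$gene_id)
  ex <- merge(exons, genes[, .(gene_id, g_strand = strand)], by = "gene_id")
  gr_e <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start, ex$end),
                                 strand = ex$g_strand)
  S4Vectors::mcols(gr_e) <- S4Vectors::DataFrame(
    source = "aluedit_sim", type = "exon", gene_id = ex$gene_id,
    gene_name = ex$gene_id,
    transcript_id = paste0(ex$gene_id, ".t1"),
    exon_number = ex$exon_number)
  rtracklayer::export(c(gr_g, gr_e), path, format = "gtf")
  invisible(path)
}

write_repeat_bed <- function(repeats, path) {
  if (nrow(repeats) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.table::data.table(chrom = repeats$chrom,
                                start = repeats$start - 1L,  # 0-based
                                end = repeats$end,
                                name = repeats$name, score = 0L,
                                strand = repeats$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

write_snp_vcf <- function(snps, path, cdna_key = "CDNA") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Variant discovered using a cDNA template\">",
                   cdna_key),
           "##INFO=<ID=COMMON,Number=0,Type=Flag,Description=\"Common variant\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- character(0)
  if (nrow(snps)) {
    info <- ifelse(snps$cdna, paste0("COMMON;", cdna_key), "COMMON")
    rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", snps$chrom, snps$pos,
                   snps$snp_id, snps$ref, snps$alt, info)
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SNP catalog from VCF
#'
#' @param path VCF file.
#' @param cdna_key INFO flag marking cDNA-template-derived records (these
#'   are exempt from SNP exclusion).
#' @return data.table: chrom, pos, cdna.
#' @export
read_snp_catalog <- function(path, cdna_key = "CDNA") {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  cdna <- if (cdna_key %in% colnames(info)) {
    v <- info[[cdna_key]]
    if (is.logical(v)) v else lengths(v) > 0L
  } else rep(FALSE, length(rr))
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(rr)),
                         pos = GenomicRanges::start(rr),
                         cdna = as.logical(cdna))
}

#' Write per-sample coordinate-sorted, indexed BAM files
#'
#' @param reads alignment table from [simulate_alignments()].
#' @param genome a `sim_genome` (for contig lengths in the header).
#' @param dir output directory.
#' @return named character vector of BAM paths, one per sample.
#' @export
write_sample_bams <- function(reads, genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- names(genome$seq)
  lens <- nchar(genome$seq)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs, lens))
  samples <- unique(reads$sample_id)
  out <- character(0)
  for (smp in samples) {
    r <- data.table::copy(reads[sample_id == smp])
    r[, `:=`(mpos = rev(pos), mrev = rev(strand == "-")), by = read_id]
    flag <- 1L + 2L +
      16L * (r$strand == "-") + 32L * r$mrev +
      64L * (r$mate == 1L) + 128L * (r$mate == 2L) +
      1024L * r$dup
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s\tNH:i:%d",
                   r$read_id, flag, r$chrom, r$pos, r$mapq, r$cigar,
                   r$mpos, r$seq, r$qual, r$nh)
    sam <- file.path(dir, paste0(smp, ".sam"))
    writeLines(c(hdr, rec), sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, smp), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    out[smp] <- bam
  }
  out
}

#' Read alignments from a BAM file into the package's record table
#'
#' @param path BAM file (duplicate-marked upstream; NH occupancy tags are
#'   honored when present).
#' @param sample_id sample label to attach.
#' @return data.table in the layout of [simulate_alignments()].
#' @export
read_alignments <- function(path, sample_id) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual"),
    tag = "NH")
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  keep <- !is.na(res$pos)
  flag <- res$flag[keep]
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$flag))
  data.table::data.table(
    sample_id = sample_id,
    read_id = res$qname[keep],
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = as.character(res$rname[keep]),
    pos = res$pos[keep],
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = res$mapq[keep],
    nh = nh[keep],
    dup = bitwAnd(flag, 1024L) > 0L,
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep])
}

#' Read gene and exon annotation from GTF
#'
#' @param path GTF file with `gene` and `exon` records carrying `gene_id`.
#' @return list with `genes` and `exons` data.tables (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  dt <- data.table::as.data.table(gr)
  genes <- dt[type == "gene",
              .(gene_id, chrom = as.character(seqnames), start, end,
                strand = as.character(strand))]
  exons <- dt[type == "exon",
              .(gene_id, chrom = as.character(seqnames), start, end,
                strand = as.character(strand))]
  if (nrow(genes) == 0L && nrow(exons)) {
    genes <- exons[, .(chrom = chrom[1L], start = min(start), end = max(end),
                       strand = strand[1L]), by = gene_id]
  }
  list(genes = genes, exons = exons)
}

#' Read a repeat annotation from BED
#'
#' @param path BED file (0-based half-open; subfamily in the name field).
#' @return data.table: chrom, start, end (1-based inclusive), name, strand.
#' @export
read_repeat_annotation <- function(path) {
  if (file.size(path) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  strand = character()))
  gr <- rtracklayer::import(path, format = "bed")
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr),
                         name = gr$name,
                         strand = as.character(GenomicRanges::strand(gr)))
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_reference <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  out <- as.character(dna)
  out
}
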
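#' Positional (end-proximity) site filter
#'
#' A candidate site fails when mismatches sit within `end_distance` nt of
#' either read end (terminal base = distance 1) in strictly more than half of
#' the mismatch-carrying reads.
#'
#' @param n_mismatch number of mismatch-carrying reads at the site.
#' @param n_end_proximal how many of those have end distance <= the window.
#' @return logical: TRUE when the site passes.
#' @export
positional_filter <- function(n_mismatch, n_end_proximal) {
  stopifnot(all(n_mismatch >= 1L), all(n_end_proximal <= n_mismatch))
  !(n_end_proximal > n_mismatch / 2)
}

#' Major-allele site filter
#'
#' With a single alternative allele the site passes outright.  With several,
#' it passes only if one allele has at least `major_allele_min` reads and
#' strictly more than `major_allele_ratio` times the reads of every other
#' alternative allele.
#'
#' @param alt_counts named integer vector of alternative-allele read counts.
#' @param params a [pipeline_params()] list.
#' @return list with `pass` (logical) and `major` (allele name or NA).
#' @export
major_allele_filter <- function(alt_counts, params = pipeline_params()) {
  stopifnot(length(alt_counts) >= 1L, !is.null(names(alt_counts)))
  if (length(alt_counts) == 1L)
    return(list(pass = TRUE, major = names(alt_counts)))
  o <- order(-alt_counts)
  top <- alt_counts[o[1]]
  rest <- alt_counts[o[-1]]
  pass <- top >= params$major_allele_min &&
    all(top > params$major_allele_ratio * rest)
  list(pass = pass, major = if (pass) names(alt_counts)[o[1]] else NA_character_)
}

#' Variant class on the transcribed strand
#'
#' When the transcribed strand is "-", both reference and alternate bases are
#' complemented before forming the class, so a genomic T>C on a minus-strand
#' transcript reports as A>G and a genomic G>A as C>T.
#'
#' @param ref,alt genomic reference and alternate bases.
#' @param tx_strand transcribed strand, "+" or "-".
#' @return character vector of classes like "A>G".
#' @export
classify_variant <- function(ref, alt, tx_strand) {
  n <- max(length(ref), length(alt), length(tx_strand))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  tx_strand <- rep_len(tx_strand, n)
  r <- ifelse(tx_strand == "-", comp_base(ref), ref)
  a <- ifelse(tx_strand == "-", comp_base(alt), alt)
  paste0(r, ">", a)
}

#' Call editing sites from one sample's pileup
#'
#' Applies, in order: the positional end-proximity filter, the major-allele
#' rule, the minimum alternate-read threshold (>= `min_alt_reads`), common-SNP
#' exclusion (catalog records flagged as cDNA-template-derived are exempt),
#' and strand-aware typing by majority vote of the transcribed-strand votes
#' of the reads carrying the major alternate allele (exact ties drop the
#' site).
#'
#' @param pileup an `editing_pileup` from [build_pileup()].
#' @param snps SNP catalog: data.table with chrom, pos and logical `cdna`
#'   columns (NULL for no exclusion).
#' @param sample_id sample label attached to the calls.
#' @param params a [pipeline_params()] list.
#' @return data.table of calls: sample_id, chrom, pos, tx_strand, class,
#'   ref, alt (genomic bases), ref_reads, alt_reads, level.  The attribute
#'   `"dropped"` tabulates drop reasons.
#' @export
call_editing_sites <- function(pileup, snps = NULL, sample_id = "sample",
                               params = pipeline_params()) {
  stopifnot(inherits(pileup, "editing_pileup"))
  al <- pileup$alleles
  mm <- pileup$mm
  empty <- data.table::data.table(
    sample_id = character(), chrom = character(), pos = integer(),
    tx_strand = character(), class = character(), ref = character(),
    alt = character(), ref_reads = integer(), alt_reads = integer(),
    level = numeric())
  if (nrow(al) == 0L) return(empty)

  prox <- mm[, .(n_mm = .N,
                 n_prox = sum(end_dist <= params$end_distance)),
             by = .(chrom, gpos)]
  drop <- c(positional = 0L, major_allele = 0L, min_alt = 0L, snp = 0L,
            strand_tie = 0L)

  prox[, pos_pass := positional_filter(n_mm, n_prox)]
  drop["positional"] <- sum(!prox$pos_pass)
  keep1 <- prox[pos_pass == TRUE, .(chrom, gpos)]

  alt_tab <- al[base != ref][keep1, on = c("chrom", "gpos"), nomatch = NULL]
  site_major <- alt_tab[, {
    cnt <- stats::setNames(n, base)
    mj <- major_allele_filter(cnt, params)
    list(ref = ref[1L], major = mj$major, pass = mj$pass,
         alt_reads = if (mj$pass) cnt[[mj$major]] else NA_integer_)
  }, by = .(chrom, gpos)]
  drop["major_allele"] <- sum(!site_major$pass)
  site_major <- site_major[pass == TRUE]

  drop["min_alt"] <- sum(site_major$alt_reads < params$min_alt_reads)
  site_major <- site_major[alt_reads >= params$min_alt_reads]

  if (!is.null(snps) && nrow(site_major)) {
    excl <- snps[cdna == FALSE, .(chrom, gpos = pos)]
    hit <- site_major[excl, on = c("chrom", "gpos"), which = TRUE,
                      nomatch = NULL]
    drop["snp"] <- length(unique(hit))
    if (length(hit)) site_major <- site_major[-unique(hit)]
  }

  if (nrow(site_major) == 0L) {
    attr(empty, "dropped") <- drop
    return(empty)
  }

  votes <- mm[site_major[, .(chrom, gpos, major)], on = c("chrom", "gpos"),
              nomatch = NULL][base == major]
  vt <- votes[, .(n_plus = sum(tx_vote == "+"),
                  n_minus = sum(tx_vote == "-")), by = .(chrom, gpos)]
  vt[, tx_strand := data.table::fifelse(n_plus > n_minus, "+",
                                        data.table::fifelse(n_minus > n_plus,
                                                            "-", "ambiguous"))]
  drop["strand_tie"] <- sum(vt$tx_strand == "ambiguous")
  site_major <- merge(site_major, vt[, .(chrom, gpos, tx_strand)],
                      by = c("chrom", "gpos"))
  site_major <- site_major[tx_strand != "ambiguous"]

  refn <- al[base == ref, .(chrom, gpos, ref_reads = n)]
  calls <- merge(site_major, refn, by = c("chrom", "gpos"), all.x = TRUE)
  calls[is.na(ref_reads), ref_reads := 0L]
  calls[, `:=`(sample_id = sample_id,
               class = classify_variant(ref, major, tx_strand),
               level = alt_reads / (ref_reads + alt_reads))]
  out <- calls[, .(sample_id, chrom, pos = gpos, tx_strand, class, ref,
                   alt = major, ref_reads, alt_reads, level)]
  data.table::setorder(out, chrom, pos)
  attr(out, "dropped") <- drop
  out
}

#' Consolidate calls across samples
#'
#' A position is retained only when every sample calling it agrees on both
#' variant class and transcribed strand, and the calls span at least
#' `min_patients` distinct patients (either tissue qualifies).
#'
#' @param calls rbind of per-sample call tables.
#' @param sample_sheet data.table with sample_id, patient_id (and more).
#' @param params a [pipeline_params()] list.
#' @return list of class `consolidated_sites`: `sites` (chrom, pos, class,
#'   tx_strand, ref, alt, n_patients, n_samples) and `calls` (member calls at
#'   the retained sites, with patient_id attached).
#' @export
consolidate_sites <- function(calls, sample_sheet,
                              params = pipeline_params()) {
  miss <- setdiff(unique(calls$sample_id), sample_sheet$sample_id)
  if (length(miss))
    stop("samples missing from the sample sheet: ",
         paste(miss, collapse = ", "))
  x <- merge(calls, sample_sheet[, .(sample_id, patient_id)],
             by = "sample_id", sort = FALSE)
  agg <- x[, .(consistent = data.table::uniqueN(class) == 1L &&
                 data.table::uniqueN(tx_strand) == 1L,
               class = class[1L], tx_strand = tx_strand[1L],
               ref = ref[1L], alt = alt[1L],
               n_patients = data.table::uniqueN(patient_id),
               n_samples = .N),
           by = .(chrom, pos)]
  sites <- agg[consistent == TRUE & n_patients >= params$min_patients,
               .(chrom, pos, class, tx_strand, ref, alt, n_patients,
                 n_samples)]
  data.table::setorder(sites, chrom, pos)
  member <- x[sites[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  structure(list(sites = sites, calls = member), class = "consolidated_sites")
}

#' Annotate sites with Alu, intron and gene context
#'
#' `in_alu` marks positions inside a repeat interval whose name starts with
#' "Alu"; `in_intron` marks positions inside a gene body but in no exon;
#' `gene_id` is the hosting gene (comma-separated if several overlap).
#'
#' @param sites data.table with chrom and pos columns.
#' @param repeats data.table with chrom, start, end, name (1-based
#'   inclusive).
#' @param genes data.table with gene_id, chrom, start, end.
#' @param exons data.table with gene_id, chrom, start, end.
#' @return the sites table with in_alu, in_intron, gene_id columns added.
#' @export
annotate_sites <- function(sites, repeats, genes, exons) {
  out <- data.table::copy(sites)
  if (nrow(out) == 0L) {
    out[, `:=`(in_alu = logical(), in_intron = logical(),
               gene_id = character())]
    return(out)
  }
  gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
  alu <- repeats[startsWith(name, "Alu")]
  gr_alu <- GenomicRanges::GRanges(alu$chrom,
                                   IRanges::IRanges(alu$start, alu$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  gr_exon <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start, exons$end))
  out[, in_alu := IRanges::overlapsAny(gr, gr_alu)]
  in_gene <- IRanges::overlapsAny(gr, gr_gene)
  in_exon <- IRanges::overlapsAny(gr, gr_exon)
  out[, in_intron := in_gene & !in_exon]
  ov <- GenomicRanges::findOverlaps(gr, gr_gene)
  gid <- tapply(genes$gene_id[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov),
                function(g) paste(sort(unique(g)), collapse = ","))
  out[, gene_id := NA_character_]
  out[as.integer(names(gid)), gene_id := unname(gid)]
  out[]
}

#' Editing sites per million mapped reads
#'
#' @param n_sites number of called A>G sites (or a calls table, in which case
#'   its `class == "A>G"` rows are counted).
#' @param total_mapped_reads total mapped reads of the sample.
#' @return normalized site count.
#' @export
sites_per_million <- function(n_sites, total_mapped_reads) {
  if (is.data.frame(n_sites)) n_sites <- sum(n_sites$class == "A>G")
  if (total_mapped_reads <= 0) stop("'total_mapped_reads' must be positive")
  n_sites * 1e6 / total_mapped_reads
}
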
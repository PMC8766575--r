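#' Parse CIGAR strings into an operation table
#'
#' @param cigar character vector of CIGAR strings.
#' @return data.table with columns `idx` (element of `cigar`), `op`, `len`.
#'   `=`/`X` are normalized to `M`.
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar, perl = TRUE)
  tok <- regmatches(cigar, m)
  bad <- which(vapply(seq_along(cigar), function(i) {
    paste0(tok[[i]], collapse = "") != cigar[i] || !length(tok[[i]])
  }, logical(1)))
  if (length(bad))
    stop("malformed CIGAR in record(s): ", paste(head(bad, 5), collapse = ", "),
         " ('", cigar[bad[1]], "')")
  n_op <- lengths(tok)
  tok <- unlist(tok, use.names = FALSE)
  ops <- data.table::data.table(
    idx = rep(seq_along(cigar), n_op),
    op = substr(tok, nchar(tok), nchar(tok)),
    len = as.integer(substr(tok, 1L, nchar(tok) - 1L)))
  ops[op %in% c("=", "X"), op := "M"]
  ops[]
}

#' Total nucleotides inside homopolymer runs of a read sequence
#'
#' A homopolymer is a maximal run of 4 or more identical bases in the read's
#' own sequence; the statistic is the summed length of all such runs.
#'
#' @param seq character vector of read sequences.
#' @return integer vector of summed run lengths.
#' @export
homopolymer_content <- function(seq) {
  m <- gregexpr("(.)\\1{3,}", seq, perl = TRUE)
  vapply(m, function(x) {
    if (x[1] == -1L) 0L else sum(attr(x, "match.length"))
  }, integer(1))
}

#' Apply the five read-level exclusion rules
#'
#' A read is excluded if it (i) is flagged as a PCR duplicate, (ii) is
#' multi-mapped (occupancy tag > 1 and/or mapping quality below the unique
#' value, per `multimap_rule`), (iii) has 5 or more clipped nucleotides
#' (soft + hard, both ends summed), (iv) has more than 10 nucleotides inside
#' homopolymer runs of 4+ identical bases, or (v) carries any insertion or
#' deletion.  A read is kept exactly when no reason applies.
#'
#' @param reads data.table of alignment records (see [simulate_alignments()]
#'   or [read_alignments()]).
#' @param params a [pipeline_params()] list.
#' @return data.table with one row per read: read_id, mate, the five boolean
#'   reason columns (duplicate, multimapped, clipped, homopolymer, indel) and
#'   `kept`.
#' @export
evaluate_reads <- function(reads, params = pipeline_params()) {
  ops <- parse_cigar(reads$cigar)
  clip_len <- integer(nrow(reads))
  cl <- ops[op %in% c("S", "H"), .(n = sum(len)), by = idx]
  clip_len[cl$idx] <- cl$n
  has_indel <- logical(nrow(reads))
  has_indel[unique(ops[op %in% c("I", "D"), idx])] <- TRUE

  multi_tag <- !is.na(reads$nh) & reads$nh > 1L
  multi_mapq <- reads$mapq < params$unique_mapq
  multimapped <- switch(params$multimap_rule,
                        tag = multi_tag,
                        mapq = multi_mapq,
                        either = multi_tag | multi_mapq)

  v <- data.table::data.table(
    read_id = reads$read_id,
    mate = reads$mate,
    duplicate = reads$dup,
    multimapped = multimapped,
    clipped = clip_len >= 5L,
    homopolymer = homopolymer_content(reads$seq) > 10L,
    indel = has_indel)
  v[, kept := !(duplicate | multimapped | clipped | homopolymer | indel)]
  v[]
}

#' Expand kept alignments into per-base records
#'
#' Walks each read's CIGAR and emits one record per aligned (M) base with its
#' read offset, genome position, base, Phred quality, end distance (distance
#' in nt to the nearer read end in read coordinates, terminal base = 1) and
#' the read's transcribed-strand vote.  Under the reverse-stranded protocol
#' mate 2 votes its own genome strand and mate 1 votes the opposite.
#'
#' @param reads data.table of alignment records (kept reads).
#' @param params a [pipeline_params()] list.
#' @return data.table with columns sample_id, ridx, mate, strand, tx_vote,
#'   read_off (0-based offset in the read sequence), gpos (1-based genome
#'   position), base, qual (integer Phred), end_dist.
#' @export
expand_aligned_bases <- function(reads, params = pipeline_params()) {
  if (nrow(reads) == 0L)
    return(data.table::data.table(sample_id = character(), chrom = character(),
                                  ridx = integer(),
                                  mate = integer(), strand = character(),
                                  tx_vote = character(), read_off = integer(),
                                  gpos = integer(), base = character(),
                                  qual = integer(), end_dist = integer()))
  ops <- parse_cigar(reads$cigar)
  # per-op cumulative offsets within each read
  ops[, read_consume := len * (op %in% c("M", "I", "S"))]
  ops[, gen_consume := len * (op %in% c("M", "D", "N"))]
  ops[, read_start := cumsum(data.table::shift(read_consume, fill = 0L)),
      by = idx]
  ops[, gen_start := cumsum(data.table::shift(gen_consume, fill = 0L)),
      by = idx]
  mseg <- ops[op == "M"]
  if (nrow(mseg) == 0L)
    stop("no aligned (M) segments among the given reads")

  seg_read0 <- mseg$read_start            # 0-based offset of segment in read
  seg_gpos <- reads$pos[mseg$idx] + mseg$gen_start
  n <- mseg$len
  within <- sequence(n) - 1L
  bases <- data.table::data.table(
    ridx = rep(mseg$idx, n),
    read_off = rep(seg_read0, n) + within,
    gpos = rep(seg_gpos, n) + within)

  # pull base and quality characters via one concatenated string per field
  seq_cat <- paste0(substring(reads$seq[mseg$idx], seg_read0 + 1L,
                              seg_read0 + n), collapse = "")
  qual_cat <- paste0(substring(reads$qual[mseg$idx], seg_read0 + 1L,
                               seg_read0 + n), collapse = "")
  bases[, base := strsplit(seq_cat, "", fixed = TRUE)[[1L]]]
  bases[, qual := phred_ints(qual_cat)]

  rlen <- nchar(reads$seq)
  bases[, `:=`(sample_id = reads$sample_id[ridx],
               chrom = reads$chrom[ridx],
               mate = reads$mate[ridx],
               strand = reads$strand[ridx])]
  bases[, end_dist := pmin(read_off + 1L, rlen[ridx] - read_off)]
  if (params$strandedness == "reverse") {
    bases[, tx_vote := ifelse(mate == 2L, strand, flip_strand(strand))]
  } else {
    bases[, tx_vote := ifelse(mate == 1L, strand, flip_strand(strand))]
  }
  if (params$dedup_overlap) {
    # overlapping mates of one fragment: count each position once (mate 2,
    # the transcribed-strand mate under the reverse protocol, wins)
    frag <- reads$read_id
    data.table::setorder(bases, -mate)
    bases <- bases[!duplicated(data.table::data.table(f = frag[bases$ridx],
                                                      g = bases$gpos))]
  }
  data.table::setcolorder(bases, c("sample_id", "chrom", "ridx", "mate",
                                   "strand", "tx_vote", "read_off", "gpos",
                                   "base", "qual", "end_dist"))
  bases[]
}

#' Build a quality-aware mismatch pileup
#'
#' Counts quality-passing bases (Phred strictly greater than `min_qual`) per
#' allele at every genome position carrying at least one quality-passing
#' mismatch, and records, for each mismatch-carrying read, its end distance
#' and transcribed-strand vote.
#'
#' @param bases per-base table from [expand_aligned_bases()] (kept reads
#'   only).
#' @param ref_seq reference sequence: a named character vector (one contig)
#'   as in `simulate_genome()$seq`, or a `Biostrings::DNAStringSet`.
#' @param params a [pipeline_params()] list.
#' @return list of class `editing_pileup`: `alleles` (gpos, ref, base, n),
#'   `mm` (one row per quality-passing mismatch read: gpos, base, end_dist,
#'   tx_vote, strand) and `params`.
#' @export
build_pileup <- function(bases, ref_seq, params = pipeline_params()) {
  ref_chr <- as_ref_strings(ref_seq)
  if (nrow(bases)) {
    miss <- setdiff(unique(bases$chrom), names(ref_chr))
    if (length(miss))
      stop("contig(s) absent from the reference: ", paste(miss, collapse = ", "))
    lims <- bases[, .(lo = min(gpos), hi = max(gpos)), by = chrom]
    if (any(lims$lo < 1L | lims$hi > nchar(ref_chr[lims$chrom])))
      stop("aligned position outside the reference sequence")
  }
  qb <- bases[qual > params$min_qual & base %in% BASES]
  qb[, ref := substring(ref_chr[chrom], gpos, gpos)]
  qb[, mism := base != ref]
  qb[, any_mm := any(mism), by = .(chrom, gpos)]
  qb <- qb[any_mm == TRUE]
  alleles <- qb[, .(n = .N), by = .(chrom, gpos, ref, base)]
  mm <- qb[mism == TRUE, .(chrom, gpos, ref, base, end_dist, tx_vote, strand)]
  data.table::setkey(alleles, chrom, gpos)
  data.table::setkey(mm, chrom, gpos)
  structure(list(alleles = alleles, mm = mm, params = params),
            class = "editing_pileup")
}

as_ref_strings <- function(ref_seq) {
  if (methods::is(ref_seq, "DNAStringSet")) {
    out <- as.character(ref_seq)
    if (is.null(names(out))) stop("reference sequences must be named")
    out
  } else if (is.character(ref_seq)) {
    if (is.null(names(ref_seq))) stop("reference sequences must be named")
    ref_seq
  } else stop("unsupported reference type: ", class(ref_seq)[1])
}
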
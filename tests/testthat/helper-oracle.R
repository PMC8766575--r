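# Naive, independent re-implementations used as oracles.  Everything here
# is written loop-by-loop from the method's rules, deliberately avoiding the
# package's vectorized code paths.

# ---- read filters ----------------------------------------------------------

oracle_cigar_walk <- function(cigar) {
  ops <- list()
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) num <- paste0(num, ch)
    else {
      ops[[length(ops) + 1L]] <- list(op = ch, len = as.integer(num))
      num <- ""
    }
  }
  ops
}

oracle_homopolymer_total <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  sum(r$lengths[r$lengths >= 4L])
}

oracle_verdict_one <- function(read, unique_mapq = 255L) {
  ops <- oracle_cigar_walk(read$cigar)
  clip <- 0L; indel <- FALSE
  for (o in ops) {
    if (o$op %in% c("S", "H")) clip <- clip + o$len
    if (o$op %in% c("I", "D")) indel <- TRUE
  }
  reasons <- character(0)
  if (isTRUE(read$dup)) reasons <- c(reasons, "duplicate")
  if ((!is.na(read$nh) && read$nh > 1L) || read$mapq < unique_mapq)
    reasons <- c(reasons, "multimapped")
  if (clip >= 5L) reasons <- c(reasons, "clipped")
  if (oracle_homopolymer_total(read$seq) > 10L)
    reasons <- c(reasons, "homopolymer")
  if (indel) reasons <- c(reasons, "indel")
  reasons
}

oracle_verdicts <- function(reads, unique_mapq = 255L) {
  kept <- logical(nrow(reads))
  for (i in seq_len(nrow(reads)))
    kept[i] <- length(oracle_verdict_one(as.list(reads[i, ]),
                                         unique_mapq)) == 0L
  kept
}

# per-base records of one read by direct CIGAR walk; read coordinates are
# positions in the read's own sequence (terminal base = distance 1)
oracle_read_bases <- function(read) {
  ops <- oracle_cigar_walk(read$cigar)
  roff <- 0L; gpos <- read$pos
  rl <- nchar(read$seq)
  seq_v <- strsplit(read$seq, "")[[1]]
  qual_v <- utf8ToInt(read$qual) - 33L
  off1s <- integer(0); gposs <- integer(0)
  for (o in ops) {
    if (o$op == "M") {
      off1s <- c(off1s, roff + seq_len(o$len))
      gposs <- c(gposs, gpos + seq_len(o$len) - 1L)
      roff <- roff + o$len; gpos <- gpos + o$len
    } else if (o$op %in% c("I", "S")) {
      roff <- roff + o$len
    } else if (o$op %in% c("D", "N")) {
      gpos <- gpos + o$len
    }
  }
  data.frame(chrom = read$chrom, gpos = gposs, base = seq_v[off1s],
             qual = qual_v[off1s],
             end_dist = pmin(off1s, rl - off1s + 1L),
             tx_vote = if (read$mate == 2L) read$strand
                       else if (read$strand == "+") "-" else "+",
             stringsAsFactors = FALSE)
}

# full naive caller for one sample: returns calls data.frame
oracle_call_sample <- function(reads, ref, snps = NULL, min_qual = 20L,
                               min_alt = 3L, end_window = 5L,
                               major_min = 5L, major_ratio = 2) {
  kept <- oracle_verdicts(reads)
  reads <- reads[kept, ]
  recs <- list()
  for (i in seq_len(nrow(reads)))
    recs[[i]] <- oracle_read_bases(as.list(reads[i, ]))
  bases <- do.call(rbind, recs)
  bases <- bases[bases$qual > min_qual & bases$base %in% c("A", "C", "G", "T"), ]
  bases$ref <- substring(ref[bases$chrom], bases$gpos, bases$gpos)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  mm_pos <- unique(bases[bases$base != bases$ref, c("chrom", "gpos")])
  idx_by_key <- split(seq_len(nrow(bases)), paste(bases$chrom, bases$gpos))
  calls <- list()
  for (r in seq_len(nrow(mm_pos))) {
    ch <- mm_pos$chrom[r]; p <- mm_pos$gpos[r]
    at <- bases[idx_by_key[[paste(ch, p)]], ]
    rb <- at$ref[1]
    mm <- at[at$base != rb, ]
    # positional filter
    if (sum(mm$end_dist <= end_window) > nrow(mm) / 2) next
    # major-allele rule
    cnt <- table(mm$base)
    if (length(cnt) > 1L) {
      top <- max(cnt)
      winner <- names(cnt)[cnt == top]
      if (length(winner) > 1L) next
      if (top < major_min) next
      if (any(top <= major_ratio * cnt[names(cnt) != winner])) next
      major <- winner
    } else major <- names(cnt)
    alt_n <- as.integer(cnt[major])
    if (alt_n < min_alt) next
    # SNP exclusion (cDNA-derived records exempt)
    if (!is.null(snps) &&
        any(snps$chrom == ch & snps$pos == p & !snps$cdna)) next
    # strand vote over major-allele mismatch reads
    votes <- mm$tx_vote[mm$base == major]
    np <- sum(votes == "+"); nm <- sum(votes == "-")
    if (np == nm) next
    strand <- if (np > nm) "+" else "-"
    refb <- if (strand == "-") comp[[rb]] else rb
    altb <- if (strand == "-") comp[[major]] else major
    ref_n <- sum(at$base == rb)
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = ch, pos = p, tx_strand = strand,
      class = paste0(refb, ">", altb), ref = rb, alt = major,
      ref_reads = ref_n, alt_reads = alt_n,
      level = alt_n / (ref_n + alt_n), stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(chrom = character(), pos = integer(),
                      tx_strand = character(), class = character(),
                      ref = character(), alt = character(),
                      ref_reads = integer(), alt_reads = integer(),
                      level = numeric()))
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$pos), ]
}

oracle_consolidate <- function(calls_by_sample, sheet, min_patients = 2L) {
  all_calls <- do.call(rbind, lapply(names(calls_by_sample), function(s) {
    d <- calls_by_sample[[s]]
    if (nrow(d)) cbind(d, sample_id = s) else NULL
  }))
  keyset <- unique(all_calls[, c("chrom", "pos")])
  kept <- list()
  for (r in seq_len(nrow(keyset))) {
    sel <- all_calls[all_calls$chrom == keyset$chrom[r] &
                       all_calls$pos == keyset$pos[r], ]
    if (length(unique(sel$class)) != 1L) next
    if (length(unique(sel$tx_strand)) != 1L) next
    pats <- unique(sheet$patient_id[match(sel$sample_id, sheet$sample_id)])
    if (length(pats) < min_patients) next
    kept[[length(kept) + 1L]] <- data.frame(
      chrom = keyset$chrom[r], pos = keyset$pos[r], class = sel$class[1],
      tx_strand = sel$tx_strand[1], stringsAsFactors = FALSE)
  }
  if (!length(kept))
    return(data.frame(chrom = character(), pos = integer(),
                      class = character(), tx_strand = character()))
  out <- do.call(rbind, kept)
  out[order(out$chrom, out$pos), ]
}

# ---- beta-binomial ---------------------------------------------------------

# term-by-term log-Gamma identity: B(k+a, n-k+b)/B(a,b) expands into
# ascending-factorial products evaluated one factor at a time
oracle_bb_logpmf <- function(k, n, a, b) {
  acc <- lchoose(n, k)
  for (j in seq_len(k)) acc <- acc + log(a + j - 1)
  for (j in seq_len(n - k)) acc <- acc + log(b + j - 1)
  for (j in seq_len(n)) acc <- acc - log(a + b + j - 1)
  acc
}

oracle_bb_loglik <- function(k, n, mu, rho) {
  tot <- 0
  for (i in seq_along(k)) {
    a <- mu[i] * (1 - rho) / rho
    b <- (1 - mu[i]) * (1 - rho) / rho
    tot <- tot + oracle_bb_logpmf(k[i], n[i], a, b)
  }
  tot
}

# ---- multiple testing ------------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in seq(m, 1L)) {
    val <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# ---- Fisher exact ----------------------------------------------------------

# exhaustive enumeration over all tables with the observed margins; table
# probabilities from factorials, two-sided p sums probabilities <= observed
# (with the conventional 1 + 1e-7 relative tolerance)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  }
  probs <- vapply(lo:hi, function(x) exp(logp(x)), numeric(1))
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
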
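#' Per-sample read counts at consolidated sites
#'
#' For every consolidated site and every sample, counts the quality-passing
#' reads supporting the (genomic) alternate allele (k) and the informative
#' total (reference + alternate supporting reads, n).  These are the
#' success/trial pairs modeled by the beta-binomial tests, available for all
#' samples whether or not the site was called in them.
#'
#' @param bases per-base table from [expand_aligned_bases()] over kept reads
#'   of all samples (column sample_id distinguishes them).
#' @param sites data.table with chrom, pos, ref, alt (genomic bases), e.g.
#'   `consolidate_sites()$sites`.
#' @param params a [pipeline_params()] list.
#' @return data.table: chrom, pos, sample_id, k, n.
#' @export
count_site_observations <- function(bases, sites, params = pipeline_params()) {
  sl <- sites[, .(chrom, gpos = pos, ref, alt)]
  qb <- bases[qual > params$min_qual][sl, on = c("chrom", "gpos"),
                                      nomatch = NULL]
  out <- qb[, .(k = sum(base == alt), n = sum(base == ref | base == alt)),
            by = .(chrom, pos = gpos, sample_id)]
  data.table::setorder(out, chrom, pos, sample_id)
  out[]
}

#' Select the test sites of one pathology
#'
#' The sites entering differential testing for a pathology are exactly those
#' called in every patient of that pathology (a call in either tissue of the
#' patient counts).
#'
#' @param consolidated a `consolidated_sites` object.
#' @param sample_sheet cohort sample sheet.
#' @param pathology pathology label.
#' @return data.table of retained sites (chrom, pos, class, tx_strand, ref,
#'   alt) with an `n_patients_pathology` attribute.
#' @export
select_test_sites <- function(consolidated, sample_sheet, pathology) {
  stopifnot(inherits(consolidated, "consolidated_sites"))
  if (!pathology %in% sample_sheet$pathology)
    stop("unknown pathology label: ", pathology)
  pats <- unique(sample_sheet$patient_id[sample_sheet$pathology == pathology])
  calls <- consolidated$calls
  cov <- calls[patient_id %in% pats,
               .(n_pat = data.table::uniqueN(patient_id)),
               by = .(chrom, pos)]
  keep <- cov[n_pat == length(pats), .(chrom, pos)]
  out <- consolidated$sites[keep, on = c("chrom", "pos"), nomatch = NULL]
  data.table::setattr(out, "n_patients_pathology", length(pats))
  out
}

#' Differential-editing test for one pathology
#'
#' Runs the beta-binomial likelihood-ratio test (condition + patient fixed
#' effects) per site over the tumor/normal samples of one pathology, with
#' Benjamini-Hochberg adjustment across the pathology's test sites.
#'
#' @param test_sites site table from [select_test_sites()].
#' @param counts per-site per-sample counts from
#'   [count_site_observations()].
#' @param sample_sheet cohort sample sheet.
#' @param pathology pathology label.
#' @return data.table of per-site results (see [bb_diff_test()]), with
#'   chrom/pos/class columns restored.
#' @export
diff_editing <- function(test_sites, counts, sample_sheet, pathology) {
  if (nrow(test_sites) == 0L)
    stop("empty test-site set for pathology ", pathology)
  sheet <- sample_sheet[sample_sheet$pathology == pathology]
  obs <- counts[sample_id %in% sheet$sample_id][
    test_sites[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  obs <- merge(obs, sheet[, .(sample_id, condition, patient_id)],
               by = "sample_id", sort = FALSE)
  obs[, unit_id := paste0(chrom, ":", pos)]
  res <- bb_diff_test(obs)
  meta <- test_sites[, .(unit_id = paste0(chrom, ":", pos), chrom, pos,
                         class, tx_strand)]
  out <- merge(meta, res, by = "unit_id", sort = FALSE)
  path_label <- pathology
  out[, pathology := path_label]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Alu Editing Index of one sample
#'
#' The AEI is the coverage-weighted aggregate editing level over adenosines
#' (on the transcribed strand) inside Alu intervals: 100 x the sum of
#' quality-passing G-supporting reads over the sum of A+G-supporting reads
#' at those positions.  The transcribed strand of each position is resolved
#' by majority vote of the covering reads' strand votes; positions with tied
#' votes or zero informative coverage contribute nothing.
#'
#' @param bases per-base table of one sample's kept reads.
#' @param ref_seq reference (named character or DNAStringSet).
#' @param repeats repeat annotation data.table (chrom, start, end, name).
#' @param params a [pipeline_params()] list.
#' @return list of class `aei_result`: aei (percentage), edited_reads,
#'   informative_reads, n_positions.
#' @export
compute_aei <- function(bases, ref_seq, repeats, params = pipeline_params()) {
  ref_chr <- as_ref_strings(ref_seq)
  alu <- repeats[startsWith(name, "Alu")]
  if (nrow(alu) == 0L) stop("no Alu intervals in the repeat annotation")
  qb <- bases[qual > params$min_qual & base %in% BASES]
  gr <- GenomicRanges::GRanges(qb$chrom, IRanges::IRanges(qb$gpos, qb$gpos))
  gr_alu <- GenomicRanges::GRanges(alu$chrom,
                                   IRanges::IRanges(alu$start, alu$end))
  qb <- qb[IRanges::overlapsAny(gr, gr_alu)]
  if (nrow(qb) == 0L)
    stop("no quality-passing coverage inside Alu intervals")
  qb[, ref := substring(ref_chr[chrom], gpos, gpos)]
  pos_tab <- qb[, .(n_plus = sum(tx_vote == "+"),
                    n_minus = sum(tx_vote == "-"),
                    ref = ref[1L],
                    nA = sum(base == "A"), nC = sum(base == "C"),
                    nG = sum(base == "G"), nT = sum(base == "T")),
                by = .(chrom, gpos)]
  pos_tab <- pos_tab[n_plus != n_minus]
  pos_tab[, tx_strand := ifelse(n_plus > n_minus, "+", "-")]
  adeno <- pos_tab[(tx_strand == "+" & ref == "A") |
                     (tx_strand == "-" & ref == "T")]
  adeno[, edited := ifelse(tx_strand == "+", nG, nC)]
  adeno[, informative := ifelse(tx_strand == "+", nA + nG, nT + nC)]
  adeno <- adeno[informative > 0L]
  informative <- sum(adeno$informative)
  if (informative == 0L)
    stop("AEI undefined: no informative reads at Alu adenosines")
  edited <- sum(adeno$edited)
  structure(list(aei = 100 * edited / informative,
                 edited_reads = edited, informative_reads = informative,
                 n_positions = nrow(adeno)),
            class = "aei_result")
}

#' Cumulative distribution of tumor-normal level differences
#'
#' Per-site differences are the means across the pathology's patients of
#' (tumor level - normal level); the summary reports their empirical CDF and
#' two-sided paired t and Wilcoxon signed-rank tests of the per-site tumor
#' versus normal mean levels.
#'
#' @param levels data.table with columns unit_id, patient_id, condition,
#'   level; each (unit, patient) should carry both conditions.
#' @return list of class `delta_summary`: deltas (per-unit), cdf
#'   (coordinates x, F), mean_diff, t_p_value, wilcoxon_p_value, n_units.
#' @export
delta_summary <- function(levels) {
  need <- c("unit_id", "patient_id", "condition", "level")
  miss <- setdiff(need, names(levels))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  wide <- data.table::dcast(levels, unit_id + patient_id ~ condition,
                            value.var = "level", fun.aggregate = mean)
  if (!all(c("tumor", "normal") %in% names(wide)) ||
      any(is.na(wide$tumor)) || any(is.na(wide$normal)))
    stop("every (unit, patient) pair needs both tumor and normal levels")
  per_unit <- wide[, .(tumor = mean(tumor), normal = mean(normal)),
                   by = unit_id]
  per_unit[, delta := tumor - normal]
  if (nrow(per_unit) < 2L)
    stop("need at least two units for a delta summary")
  f <- stats::ecdf(per_unit$delta)
  xs <- sort(unique(per_unit$delta))
  cdf <- data.table::data.table(x = xs, F = f(xs))
  tt <- tryCatch(
    stats::t.test(per_unit$tumor, per_unit$normal, paired = TRUE),
    error = function(e) list(p.value = NA_real_))
  wt <- tryCatch(
    stats::wilcox.test(per_unit$tumor, per_unit$normal, paired = TRUE,
                       exact = FALSE),
    error = function(e) list(p.value = NA_real_))
  structure(list(deltas = per_unit, cdf = cdf,
                 mean_diff = mean(per_unit$delta),
                 t_p_value = tt$p.value, wilcoxon_p_value = wt$p.value,
                 n_units = nrow(per_unit)),
            class = "delta_summary")
}
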
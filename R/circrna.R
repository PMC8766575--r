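#' Global circular RNA level per sample (BSJ per million)
#'
#' @param junctions data.table with sample_id and backsplice_reads.
#' @param total_mapped_reads named numeric vector of mapped-read totals per
#'   sample (or a single value when `junctions` holds one sample).
#' @return data.table: sample_id, bsj_reads, bsj_per_million.
#' @export
global_circ_level <- function(junctions, total_mapped_reads) {
  tot <- junctions[, .(bsj_reads = sum(backsplice_reads)), by = sample_id]
  if (is.null(names(total_mapped_reads))) {
    if (length(total_mapped_reads) != 1L || nrow(tot) != 1L)
      stop("'total_mapped_reads' must be named per sample")
    names(total_mapped_reads) <- tot$sample_id
  }
  miss <- setdiff(tot$sample_id, names(total_mapped_reads))
  if (length(miss))
    stop("no mapped-read total for sample(s): ", paste(miss, collapse = ", "))
  depth <- total_mapped_reads[tot$sample_id]
  if (any(depth <= 0)) stop("'total_mapped_reads' must be positive")
  tot[, bsj_per_million := bsj_reads * 1e6 / depth]
  tot[]
}

#' Flag genes by circRNA signature and Alu overlap
#'
#' A gene has a circRNA signature when any sample shows at least one
#' back-splice read; it is Alu-associated when its gene body intersects at
#' least one Alu repeat interval.
#'
#' @param junctions per-gene per-sample junction counts.
#' @param genes gene table (gene_id, chrom, start, end).
#' @param repeats repeat table (chrom, start, end, name).
#' @return data.table: gene_id, has_circ_signature, overlaps_alu.
#' @export
circ_gene_flags <- function(junctions, genes, repeats) {
  sig <- junctions[, .(has_circ_signature = any(backsplice_reads > 0L)),
                   by = gene_id]
  alu <- repeats[startsWith(name, "Alu")]
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  gr_alu <- GenomicRanges::GRanges(alu$chrom,
                                   IRanges::IRanges(alu$start, alu$end))
  ov <- data.table::data.table(gene_id = genes$gene_id,
                               overlaps_alu = IRanges::overlapsAny(gr_gene,
                                                                   gr_alu))
  out <- merge(sig, ov, by = "gene_id", all = TRUE)
  out[is.na(has_circ_signature), has_circ_signature := FALSE]
  out[]
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' The exact-test route shared by the Alu-association and gene-overlap
#' tests.
#'
#' @param a,b,c,d cell counts of the table \[\[a, b\], \[c, d\]\].
#' @return the two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), 2L, 2L),
                     conf.int = FALSE)$p.value
}

#' Alu-association test between circ and non-circ genes
#'
#' Builds the 2x2 table of circRNA signature against Alu overlap and applies
#' a two-sided Fisher exact test.
#'
#' @param flags output of [circ_gene_flags()].
#' @return list of class `alu_association`: table (2x2), prop_circ,
#'   prop_noncirc (Alu-overlap proportions per group), p_value.
#' @export
alu_association_test <- function(flags) {
  tab <- table(factor(flags$has_circ_signature, levels = c(TRUE, FALSE)),
               factor(flags$overlaps_alu, levels = c(TRUE, FALSE)),
               dnn = c("circ", "alu"))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  p <- if (degenerate) {
    warning("degenerate margins in the Alu-association table; p = 1")
    1
  } else {
    fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  prop <- function(g) {
    n <- sum(flags$has_circ_signature == g)
    if (n == 0L) NA_real_
    else sum(flags$overlaps_alu[flags$has_circ_signature == g]) / n
  }
  structure(list(table = tab, prop_circ = prop(TRUE),
                 prop_noncirc = prop(FALSE), p_value = p),
            class = "alu_association")
}

#' Differential circRNA expression-rate test for one pathology
#'
#' For genes whose maximum back-splice count across the pathology's samples
#' is strictly greater than `min_bsj`, fits beta-binomial regressions of
#' back-splice reads out of total junction reads with condition and patient
#' effects, tests the condition term by likelihood ratio and adjusts by BH
#' within the pathology.
#'
#' @param junctions per-gene per-sample junction counts.
#' @param sample_sheet cohort sample sheet.
#' @param pathology pathology label.
#' @param params a [pipeline_params()] list (uses `min_bsj` and `fdr`).
#' @return data.table of per-gene results (see [bb_diff_test()]), or an
#'   empty table when no gene clears the gate.
#' @export
diff_circ_rate <- function(junctions, sample_sheet, pathology,
                           params = pipeline_params()) {
  if (!pathology %in% sample_sheet$pathology)
    stop("unknown pathology label: ", pathology)
  sheet <- sample_sheet[sample_sheet$pathology == pathology]
  jx <- junctions[sample_id %in% sheet$sample_id]
  gate <- jx[, .(max_bsj = max(backsplice_reads)), by = gene_id]
  tested <- gate[max_bsj > params$min_bsj, gene_id]
  if (!length(tested))
    return(data.table::data.table(unit_id = character(),
                                  estimate = numeric(), rho = numeric(),
                                  statistic = numeric(), p_value = numeric(),
                                  fdr_adjusted_p = numeric(),
                                  mean_tumor = numeric(),
                                  mean_normal = numeric(), diff = numeric(),
                                  degenerate = logical(),
                                  converged = logical(),
                                  pathology = character()))
  obs <- jx[gene_id %in% tested]
  obs <- merge(obs, sheet[, .(sample_id, condition, patient_id)],
               by = "sample_id", sort = FALSE)
  obs[, `:=`(unit_id = gene_id, k = backsplice_reads,
             n = backsplice_reads + linear_junction_reads)]
  res <- bb_diff_test(obs)
  path_label <- pathology
  res[, pathology := path_label]
  res[]
}

#' Overlap between differentially edited and differentially circ genes
#'
#' Intersects the two gene sets and tests the association against the
#' expressed-gene universe with a two-sided Fisher exact test.
#'
#' @param editing_genes,circ_genes character vectors of gene ids.
#' @param universe expressed-gene universe (character vector); both sets must
#'   be subsets of it.
#' @return list of class `gene_overlap`: intersection, table, p_value,
#'   n_universe.
#' @export
overlap_diff_genes <- function(editing_genes, circ_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  editing_genes <- unique(editing_genes)
  circ_genes <- unique(circ_genes)
  out1 <- setdiff(editing_genes, universe)
  out2 <- setdiff(circ_genes, universe)
  if (length(out1) || length(out2))
    stop("gene(s) absent from the universe: ",
         paste(head(c(out1, out2), 5), collapse = ", "))
  in_e <- universe %in% editing_genes
  in_c <- universe %in% circ_genes
  tab <- table(factor(in_e, levels = c(TRUE, FALSE)),
               factor(in_c, levels = c(TRUE, FALSE)),
               dnn = c("editing", "circ"))
  p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(list(intersection = intersect(editing_genes, circ_genes),
                 table = tab, p_value = p, n_universe = length(universe)),
            class = "gene_overlap")
}

#' Flanking-intron co-localization of edited sites and circRNAs
#'
#' For each gene carrying both differential editing and differential circRNA
#' signal, reports whether at least one differentially edited site lies in an
#' intron immediately adjacent to a back-splice boundary of one of the
#' gene's circRNAs (the intron ending at the circRNA's genomic start or the
#' intron starting at its genomic end).
#'
#' @param sites data.table of differentially edited sites with chrom, pos,
#'   gene_id.
#' @param circs data.table of exonic circRNAs: gene_id, chrom, circ_start,
#'   circ_end (genomic span of the circularized exons).
#' @param genes,exons gene and exon annotation tables.
#' @return list of class `flank_coloc`: per_gene (gene_id, colocalized),
#'   fraction, n_genes.
#' @export
flanking_intron_colocalization <- function(sites, circs, genes, exons) {
  shared <- intersect(unique(sites$gene_id), unique(circs$gene_id))
  if (!length(shared))
    return(structure(list(per_gene = data.table::data.table(
      gene_id = character(), colocalized = logical()),
      fraction = NA_real_, n_genes = 0L), class = "flank_coloc"))

  introns <- exons[order(gene_id, start),
                   .(i_start = head(end, -1L) + 1L,
                     i_end = utils::tail(start, -1L) - 1L), by = gene_id]
  res <- lapply(shared, function(g) {
    ge <- genes[gene_id == g]
    cc <- circs[gene_id == g]
    bad <- cc$circ_start < ge$start | cc$circ_end > ge$end
    if (any(bad)) {
      warning("circRNA boundary outside gene body for ", g,
              "; record(s) skipped")
      cc <- cc[!bad]
    }
    if (nrow(cc) == 0L)
      return(data.table::data.table(gene_id = g, colocalized = FALSE))
    gi <- introns[gene_id == g]
    flank <- unique(data.table::rbindlist(lapply(seq_len(nrow(cc)), function(i) {
      rbind(gi[i_end == cc$circ_start[i] - 1L],
            gi[i_start == cc$circ_end[i] + 1L])
    })))
    sp <- sites[gene_id == g, pos]
    hit <- nrow(flank) > 0L && length(sp) > 0L &&
      any(vapply(sp, function(p) any(p >= flank$i_start & p <= flank$i_end),
                 logical(1)))
    data.table::data.table(gene_id = g, colocalized = hit)
  })
  per_gene <- data.table::rbindlist(res)
  structure(list(per_gene = per_gene,
                 fraction = mean(per_gene$colocalized),
                 n_genes = nrow(per_gene)),
            class = "flank_coloc")
}

#' Compare editing-delta distributions between circ-defined gene groups
#'
#' Two-sided two-sample Kolmogorov-Smirnov test of per-site editing level
#' differences, split by whether the host gene shows a decreased circRNA
#' expression rate in tumors.
#'
#' @param deltas numeric vector of editing level differences.
#' @param in_decreased_group logical vector aligned with `deltas`.
#' @return list of class `delta_ks`: statistic, p_value, n1, n2.
#' @export
delta_cdf_comparison <- function(deltas, in_decreased_group) {
  stopifnot(length(deltas) == length(in_decreased_group))
  g1 <- deltas[in_decreased_group]
  g2 <- deltas[!in_decreased_group]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least two values")
  kt <- suppressWarnings(stats::ks.test(g1, g2, exact = FALSE))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n1 = length(g1), n2 = length(g2)),
            class = "delta_ks")
}
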
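#' Run the full editing + circRNA pipeline on a cohort
#'
#' Executes the complete analysis: read filtering, mismatch pileups,
#' per-sample editing calls, cross-sample consolidation, annotation,
#' per-pathology differential editing with delta summaries, the Alu Editing
#' Index, per-sample sites-per-million, and the circRNA stage (global
#' back-splice level, Alu association, per-pathology differential rates,
#' gene-overlap Fisher test, flanking-intron co-localization and the
#' KS comparison of editing deltas between circ-defined gene groups).
#' Pathologies with fewer than `params$min_patients_test` patients are
#' skipped by the differential stages unless `test_all_pathologies` is set.
#'
#' @param input a `sim_cohort` bundle (in-memory) or a `cohort_paths`-style
#'   named list of file paths (ref_fasta, genes_gtf, repeats_bed, snp_vcf,
#'   sample_sheet, junctions, circ_coords, bams = named vector per sample).
#' @param params a [pipeline_params()] list.
#' @param out_dir if non-NULL, write result tables and a manifest there.
#' @param test_all_pathologies override the minimum-patient gate.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(input, params = pipeline_params(), out_dir = NULL,
                         test_all_pathologies = FALSE) {
  st <- load_pipeline_input(input, params)
  sheet <- st$sheet

  # ---- read filtering, pileup, per-sample calls ---------------------------
  samples <- sheet$sample_id
  calls_list <- vector("list", length(samples))
  bases_list <- vector("list", length(samples))
  mapped <- stats::setNames(numeric(length(samples)), samples)
  verdict_counts <- stats::setNames(integer(length(samples)), samples)
  for (i in seq_along(samples)) {
    smp <- samples[i]
    reads <- st$reads_of(smp)
    mapped[smp] <- nrow(reads)
    v <- evaluate_reads(reads, params)
    verdict_counts[smp] <- sum(v$kept)
    bases <- expand_aligned_bases(reads[v$kept], params)
    pu <- build_pileup(bases, st$ref, params)
    calls_list[[i]] <- call_editing_sites(pu, st$snps, smp, params)
    bases_list[[i]] <- bases
  }
  calls <- data.table::rbindlist(calls_list)
  bases_all <- data.table::rbindlist(bases_list)

  # ---- consolidation and annotation ---------------------------------------
  cons <- consolidate_sites(calls, sheet, params)
  sites_ann <- annotate_sites(cons$sites, st$repeats, st$genes, st$exons)
  ag_sites <- sites_ann[class == "A>G"]
  counts <- count_site_observations(bases_all, cons$sites, params)

  # ---- per-sample summaries ----------------------------------------------
  spm <- cons$calls[class == "A>G", .(n_sites = .N), by = sample_id]
  spm <- merge(data.table::data.table(sample_id = samples), spm,
               by = "sample_id", all.x = TRUE)
  spm[is.na(n_sites), n_sites := 0L]
  spm[, sites_per_million := sites_per_million(n_sites, mapped[sample_id]),
      by = sample_id]

  aei <- data.table::rbindlist(lapply(seq_along(samples), function(i) {
    a <- tryCatch(compute_aei(bases_list[[i]], st$ref, st$repeats, params),
                  error = function(e) NULL)
    if (is.null(a))
      data.table::data.table(sample_id = samples[i], aei = NA_real_,
                             edited_reads = NA_integer_,
                             informative_reads = NA_integer_)
    else
      data.table::data.table(sample_id = samples[i], aei = a$aei,
                             edited_reads = a$edited_reads,
                             informative_reads = a$informative_reads)
  }))

  # ---- per-pathology differential editing ---------------------------------
  path_sizes <- sheet[, .(n = data.table::uniqueN(patient_id)), by = pathology]
  tested_paths <- path_sizes[n >= params$min_patients_test | test_all_pathologies,
                             pathology]
  diff_ed <- list(); deltas <- list()
  for (pl in tested_paths) {
    ts <- select_test_sites(cons, sheet, pl)
    ts <- ts[class == "A>G"]
    if (nrow(ts) == 0L) next
    diff_ed[[pl]] <- diff_editing(ts, counts, sheet, pl)
    lv <- counts[ts[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
    lv <- merge(lv, sheet[, .(sample_id, condition, patient_id, pathology)],
                by = "sample_id")
    lv <- lv[pathology == pl & n > 0]
    lv[, `:=`(unit_id = paste0(chrom, ":", pos), level = k / n)]
    deltas[[pl]] <- tryCatch(
      delta_summary(lv[, .(unit_id, patient_id, condition, level)]),
      error = function(e) NULL)
  }
  diff_editing_all <- data.table::rbindlist(diff_ed)

  # ---- circRNA stage -------------------------------------------------------
  jx <- st$junctions
  circ <- NULL
  if (!is.null(jx)) {
    flags <- circ_gene_flags(jx, st$genes, st$repeats)
    alu_assoc <- alu_association_test(flags)
    bsj_pm <- global_circ_level(jx, mapped)
    diff_circ <- data.table::rbindlist(
      lapply(tested_paths, function(pl)
        diff_circ_rate(jx, sheet, pl, params)))

    sig_ed <- data.table::data.table(gene_id = character())
    if (nrow(diff_editing_all)) {
      sig <- diff_editing_all[fdr_adjusted_p < params$fdr]
      sig_sites <- sites_ann[sig[, .(chrom, pos)], on = c("chrom", "pos"),
                             nomatch = NULL]
      sig_ed <- sig_sites[!is.na(gene_id)]
    }
    ed_genes <- unique(unlist(strsplit(sig_ed$gene_id, ",")))
    circ_genes <- if (nrow(diff_circ))
      unique(diff_circ[fdr_adjusted_p < params$fdr, unit_id]) else character()
    universe <- unique(jx$gene_id)
    overlap <- tryCatch(
      overlap_diff_genes(intersect(ed_genes, universe), circ_genes, universe),
      error = function(e) NULL)

    coloc <- NULL
    if (!is.null(st$circ_coords) && length(ed_genes) && length(circ_genes)) {
      both <- intersect(ed_genes, circ_genes)
      coloc <- flanking_intron_colocalization(
        sig_ed[gene_id %in% both], st$circ_coords[gene_id %in% both],
        st$genes, st$exons)
    }

    ks <- NULL
    if (nrow(diff_editing_all) && nrow(diff_circ)) {
      dec_genes <- unique(diff_circ[fdr_adjusted_p < params$fdr & diff < 0,
                                    unit_id])
      ed_sites <- merge(diff_editing_all,
                        sites_ann[, .(chrom, pos, gene_id)],
                        by = c("chrom", "pos"))
      ed_sites <- ed_sites[!is.na(gene_id)]
      grp <- vapply(strsplit(ed_sites$gene_id, ","), function(g)
        any(g %in% dec_genes), logical(1))
      ks <- tryCatch(delta_cdf_comparison(ed_sites$diff, grp),
                     error = function(e) NULL)
    }
    circ <- list(flags = flags, alu_association = alu_assoc,
                 bsj_per_million = bsj_pm, diff_circ = diff_circ,
                 overlap = overlap, colocalization = coloc,
                 ks_comparison = ks)
  }

  report <- structure(list(
    params = params, sample_sheet = sheet, mapped_reads = mapped,
    kept_reads = verdict_counts, calls = calls, consolidated = cons,
    sites = sites_ann, ag_sites = ag_sites, counts = counts,
    sites_per_million = spm, aei = aei,
    diff_editing = diff_editing_all, delta_summaries = deltas,
    circ = circ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Normalize the two input modes into one access structure.
load_pipeline_input <- function(input, params) {
  if (inherits(input, "sim_cohort")) {
    truth <- input$truth
    reads <- input$reads
    if (is.null(reads)) stop("cohort bundle holds no alignments")
    list(sheet = data.table::as.data.table(input$samples),
         ref = truth$genome$seq,
         genes = truth$genome$genes, exons = truth$genome$exons,
         repeats = truth$genome$repeats,
         snps = if (nrow(truth$snps)) truth$snps else NULL,
         junctions = input$junctions,
         circ_coords = truth$circ,
         reads_of = function(smp) reads[sample_id == smp])
  } else if (is.list(input)) {
    need <- c("ref_fasta", "genes_gtf", "repeats_bed", "sample_sheet", "bams")
    miss <- setdiff(need, names(input))
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    for (f in c(input$ref_fasta, input$genes_gtf, input$repeats_bed,
                input$sample_sheet, input$snp_vcf, input$junctions,
                unlist(input$bams)))
      if (!file.exists(f)) stop("input file not found: ", f)
    sheet <- data.table::fread(input$sample_sheet)
    ann <- read_gene_annotation(input$genes_gtf)
    bams <- input$bams
    if (is.null(names(bams)))
      stop("'bams' must be named by sample_id")
    list(sheet = sheet,
         ref = read_reference(input$ref_fasta),
         genes = ann$genes, exons = ann$exons,
         repeats = read_repeat_annotation(input$repeats_bed),
         snps = if (!is.null(input$snp_vcf))
           read_snp_catalog(input$snp_vcf, params$snp_cdna_key) else NULL,
         junctions = if (!is.null(input$junctions))
           data.table::fread(input$junctions) else NULL,
         circ_coords = if (!is.null(input$circ_coords))
           data.table::fread(input$circ_coords) else NULL,
         reads_of = function(smp) read_alignments(bams[[smp]], smp))
  } else stop("unsupported input type")
}

#' Validate pipeline inputs
#'
#' Checks contig-name concordance between the reference and the annotation
#' tables, coordinate sanity, and sample-sheet completeness (every sample
#' has a patient, condition in {tumor, normal}, and every patient carries
#' both tissues).  Failures are collected, not thrown.
#'
#' @param input as in [run_pipeline()].
#' @param params a [pipeline_params()] list.
#' @return character vector of failure messages (empty when valid).
#' @export
validate_inputs <- function(input, params = pipeline_params()) {
  fails <- character(0)
  st <- tryCatch(load_pipeline_input(input, params),
                 error = function(e) conditionMessage(e))
  if (is.character(st)) return(paste("load:", st))
  contigs <- names(st$ref)
  for (tab in c("genes", "exons", "repeats")) {
    d <- st[[tab]]
    if (nrow(d) == 0L) next
    bad <- setdiff(unique(d$chrom), contigs)
    if (length(bad))
      fails <- c(fails, sprintf("%s: contig(s) absent from reference: %s",
                                tab, paste(bad, collapse = ", ")))
    over <- d[d$chrom %in% contigs & d$end > nchar(st$ref[d$chrom]), ]
    if (nrow(over))
      fails <- c(fails, sprintf("%s: %d interval(s) beyond contig end",
                                tab, nrow(over)))
    if (any(d$start > d$end))
      fails <- c(fails, sprintf("%s: start > end", tab))
  }
  sheet <- st$sheet
  need <- c("sample_id", "patient_id", "condition", "pathology")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    fails <- c(fails, paste("sample sheet lacks columns:",
                            paste(miss, collapse = ", ")))
  } else {
    if (any(!sheet$condition %in% c("tumor", "normal")))
      fails <- c(fails, "sample sheet: condition must be tumor or normal")
    pair <- sheet[, .(both = all(c("tumor", "normal") %in% condition)),
                  by = patient_id]
    if (any(!pair$both))
      fails <- c(fails, paste("patient(s) without both tissues:",
                              paste(pair$patient_id[!pair$both],
                                    collapse = ", ")))
  }
  fails
}

# Write the report bundle as TSVs plus a manifest with a config hash and
# per-stage row counts; identical inputs and config reproduce identical
# files.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && nrow(x))
      data.table::fwrite(x, file.path(out_dir, name), sep = "\t")
  }
  w(report$calls, "calls.tsv")
  w(report$sites, "consolidated_sites.tsv")
  w(report$counts, "site_sample_counts.tsv")
  w(report$sites_per_million, "sites_per_million.tsv")
  w(report$aei, "aei.tsv")
  w(report$diff_editing, "diff_editing.tsv")
  for (pl in names(report$delta_summaries)) {
    ds <- report$delta_summaries[[pl]]
    if (!is.null(ds)) w(ds$cdf, sprintf("delta_cdf_%s.tsv", pl))
  }
  if (!is.null(report$circ)) {
    w(report$circ$bsj_per_million, "bsj_per_million.tsv")
    w(report$circ$diff_circ, "diff_circ.tsv")
    w(report$circ$flags, "circ_gene_flags.tsv")
  }
  cfg <- report$params
  tf <- tempfile()
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "="), tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- data.table::data.table(
    field = c("config_hash",
            paste0("threshold_", names(cfg)),
            "n_samples", "n_calls", "n_consolidated_sites", "n_ag_sites",
            "n_diff_editing_rows", "n_diff_circ_rows"),
    value = c(cfg_hash,
              vapply(cfg, function(v) paste(format(v), collapse = ","),
                     character(1)),
              nrow(report$sample_sheet), nrow(report$calls),
              nrow(report$sites), nrow(report$ag_sites),
              nrow(report$diff_editing),
              if (is.null(report$circ)) 0L else nrow(report$circ$diff_circ)))
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(out_dir)
}
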
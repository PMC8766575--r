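# Shared small cohorts, built once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, expr, envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# four patients, two pathologies, all read artifacts on
tiny_cohort <- function() cached("tiny", {
  cfg <- simulation_config(seed = 101, pathology_sizes = c(O2 = 2L, A3 = 2L),
                           n_genes = 6L, n_editing_sites = 60L,
                           n_snps = 20L)
  simulate_cohort(cfg)
})

# clean high-coverage cohort: no sequencing error, levels >= 0.2
clean_cohort <- function() cached("clean", {
  cfg <- simulation_config(seed = 202,
                           pathology_sizes = c(O2 = 2L, A3 = 2L),
                           n_genes = 10L, n_editing_sites = 200L,
                           n_snps = 50L, base_error_rate = 0,
                           frac_low_qual = 0,
                           coverage_mean = 40, site_dispersion = 0.01,
                           level_range = c(0.2, 0.95),
                           editing_level_shape = c(2, 4))
  simulate_cohort(cfg)
})

# hand-built alignment record; defaults give a clean 101M plus-strand mate 2
make_read <- function(seq, pos = 1L, cigar = paste0(nchar(seq), "M"),
                      mate = 2L, strand = "+", mapq = 255L, nh = 1L,
                      dup = FALSE, qual = strrep("F", nchar(seq)),
                      read_id = "r1", sample_id = "s1", chrom = "chrS") {
  data.table::data.table(sample_id = sample_id, read_id = read_id,
                         mate = mate, chrom = chrom, pos = pos,
                         strand = strand, mapq = mapq, nh = nh, dup = dup,
                         cigar = cigar, seq = seq, qual = qual)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a pileup with n_alt mismatch reads (mate 2, + strand) at position 11
pileup_fixture <- function(n_alt = 6L, n_ref = 10L, alt = "G",
                           n_alt2 = 0L, alt2 = "T") {
  ref <- c(chrS = strrep("ACGTT", 10))   # pos 11 is A
  stopifnot(substr(ref[[1]], 11, 11) == "A")
  mk <- function(base, i, id) {
    s <- substr(ref[[1]], 1, 40)
    substr(s, 11, 11) <- base
    make_read(s, read_id = paste0(id, i))
  }
  reads <- data.table::rbindlist(c(
    lapply(seq_len(n_ref), function(i) mk("A", i, "r")),
    lapply(seq_len(n_alt), function(i) mk(alt, i, "x")),
    if (n_alt2 > 0) lapply(seq_len(n_alt2), function(i) mk(alt2, i, "y"))))
  list(pileup = build_pileup(expand_aligned_bases(reads), ref), ref = ref)
}
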
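# aluedit

Strand-aware A-to-I RNA editing and circular RNA analysis for paired
tumor–normal RNA-seq.

## What it does and for whom

A-to-I editing (read out as A>G mismatches on the transcribed strand) and
back-splicing into circular RNA are Alu-associated, brain-enriched
post-transcriptional processes that shift in tumors relative to matched
normal tissue. `aluedit` is for computational biologists who have stranded
paired-end alignments for tumor/normal pairs and want to:

* call RNA editing sites directly from BAMs with a strict, fully specified
  filter cascade — no precompiled editing-type annotation needed;
* quantify editing levels, the Alu Editing Index (AEI), and per-gene
  circular RNA expression rates;
* test tumor–normal differences per pathology group with a statistic that
  respects patient pairing and across-patient overdispersion;
* validate the whole chain against a synthetic cohort with known ground
  truth.

## The model in brief

**Calling.** Reads flagged as PCR duplicates, multi-mapped, carrying ≥ 5
clipped nt, > 10 nt of homopolymer runs (runs of ≥ 4 identical bases), or
any indel are removed. Bases count only with Phred quality > 20. A site
survives if mismatches are not end-proximal (≤ 5 nt from a read end) in
more than half of the mismatch reads, a major alternate allele exists
(≥ 5 reads and > 2× any other alternate when several are present) with ≥ 3
supporting reads, the position is not a common SNP (cDNA-derived catalog
records exempt), and the transcribed-strand vote of the supporting reads is
unambiguous (reverse-stranded protocol: mate 2 votes its own strand).
Across samples, sites must agree on class and strand and occur in ≥ 2
patients. Editing level = alt/(ref+alt).

**Testing.** For each unit (site or gene) with successes *k* of *n* trials
(edited of informative reads; back-splice of total junction reads), a
beta-binomial regression with logit mean
`intercept + condition + patient` and shared intraclass correlation ρ is
fitted; the condition effect is tested by likelihood ratio against
χ²(1) and BH-adjusted within pathology (significant: FDR < 0.05). ρ is
estimated by a Cox–Reid adjusted profile likelihood, which removes the
downward bias that one-parameter-per-patient designs otherwise inflict on
ρ̂ (and the type-I error of the test).

**Summaries.** AEI = 100 × ΣG/(ΣA+ΣG) over transcribed-strand adenosines
in Alu intervals; sites and back-splice reads per million mapped reads;
per-pathology cumulative distributions of tumor−normal level differences
with paired t/Wilcoxon tests; Fisher exact tests for Alu association and
editing×circRNA gene overlap; Kolmogorov–Smirnov comparison of editing
deltas between circ-defined gene groups; flanking-intron co-localization.

## Worked example

```r
library(aluedit)

cfg <- simulation_config(seed = 42,
                         pathology_sizes = c(O2 = 3L, A2 = 3L),
                         n_genes = 6L, n_editing_sites = 80L, n_snps = 20L,
                         coverage_mean = 40)
cohort <- simulate_cohort(cfg)      # genome + truth + BAM-ready reads + junctions
report <- run_pipeline(cohort)

nrow(report$sites)                  # 69 consolidated sites
head(report$ag_sites[, .(pos, class, tx_strand, n_patients, in_alu, gene_id)], 3)
#>      pos  class tx_strand n_patients in_alu gene_id
#> 1:   369    A>G         +          5   TRUE    G001
#> 2:   414    A>G         +          6   TRUE    G001
#> 3:   468    A>G         +          6   TRUE    G001
report$aei[1:2]
#>    sample_id      aei edited_reads informative_reads
#> 1:      P01T 2.434622          634             26041
#> 2:      P01N 2.195483          593             27010
```

All 69 consolidated sites are class A>G (the planted signal is A-to-I; the
20 planted SNPs are removed by catalog exclusion), and they sit in intronic
Alu intervals as planted. The AEI of a few percent is the coverage-weighted
mean editing level over all Alu adenosines — most are unedited, which
dilutes the per-site levels.

```r
de <- report$diff_editing
de[pathology == "A2" & fdr_adjusted_p < 0.05,
   .(unit_id, estimate, fdr_adjusted_p, diff)]
#>      unit_id   estimate fdr_adjusted_p       diff
#> 1: chrS:1390 -0.9557672     0.03036665 -0.2239244

report$delta_summaries$A2$mean_diff    # -0.257 (planted shift: -0.30)
report$delta_summaries$O2$mean_diff    # +0.031 (planted shift: +0.04)
```

The A2 pathology (planted level shift −0.30 in tumors) shows a strongly
left-shifted delta distribution and a significantly differential site at
FDR < 0.05 even with only three patients, while O2 (planted +0.04) stays
near zero — the qualitative contrast the method is built to expose.

File-based runs work the same way: `write_cohort_files(cohort, "cohort/")`
emits FASTA/GTF/BED/VCF/BAM/TSV, and `run_pipeline()` accepts the returned
path list. A thin command-line wrapper with `simulate`, `validate` and
`report` subcommands lives at `inst/scripts/aluedit.R`.

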
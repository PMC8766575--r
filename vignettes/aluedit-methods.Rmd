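---
title: "Calling and comparing A-to-I editing and circular RNA in paired tumor-normal RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing A-to-I editing and circular RNA in paired tumor-normal RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluedit)
library(data.table)
```

## The problem

Adenosine-to-inosine (A-to-I) editing and back-splicing into circular RNA
are two post-transcriptional processes concentrated in and around Alu
elements, and both are abundant in brain tissue.  Comparing them between
tumor and matched normal tissue requires (i) calling editing sites directly
from stranded RNA-seq without relying on precompiled annotation of editing
types, (ii) quantifying per-site editing levels and per-gene circular RNA
expression rates as proportions of read counts, and (iii) testing
tumor-normal differences while respecting that the two tissues of one
patient are paired and that read-count proportions are overdispersed across
patients.

`aluedit` implements that chain: a strand-aware editing-site caller with a
strict read- and site-level filter cascade, a beta-binomial regression
engine with likelihood-ratio testing shared by the editing and circRNA
stages, the Alu Editing Index, and the cumulative-distribution and
association summaries used to compare pathology groups.  Every stage is
exercised end to end on a bundled synthetic-cohort generator with known
ground truth.

## Editing-site calling

Reads are excluded when they are flagged PCR duplicates, multi-mapped
(occupancy tag > 1 or mapping quality below the aligner's unique-mapping
value, 255 in the STAR dialect; the rule is configurable), carry 5 or more
clipped nucleotides (soft and hard clips summed over both ends), carry more
than 10 nucleotides inside homopolymer runs (a run is 4 or more identical
consecutive bases of the read's own sequence; the statistic is the total
across runs, so 10 passes and 11 fails), or contain any insertion or
deletion.  The five reasons are independent, so the verdict does not depend
on evaluation order.

Bases enter the pileup only with Phred quality strictly greater than 20.
At every position with at least one quality-passing mismatch, the caller
applies, in order:

1. **Positional filter** — the site fails when mismatches lie within 5 nt
   of either read end (distance measured in the read's own coordinates,
   terminal base = 1) in strictly more than half of the mismatch-carrying
   reads.
2. **Major-allele rule** — with several alternative alleles, one allele
   must have at least 5 reads and strictly more than twice the reads of
   every other alternative; with a single alternative the rule does not
   apply.
3. **Minimum support** — the major alternate needs at least 3 reads.
4. **SNP exclusion** — positions present in the common-SNP catalog are
   dropped, except records flagged as discovered on a cDNA template (an
   INFO flag, key configurable), which are retained.
5. **Strand assignment** — under the reverse-stranded protocol, mate 2
   votes its own genome strand and mate 1 the opposite; the site takes the
   majority vote of the reads carrying the major alternate, and exact ties
   drop the site.  On a minus-strand site both alleles are complemented, so
   a genomic T>C reports as A>G and a genomic G>A as C>T.

Across samples, a site is kept only when every sample calling it agrees on
variant class and strand, and the calls span at least two distinct patients
(either tissue counts).  The editing level of a call is
`alt / (ref + alt)` over quality-passing reads.

Two choices the method's description leaves open are fixed here and
exposed as switches: end distances are measured in read coordinates (not
alignment coordinates) when clipping exists, and overlapping mates of a
fragment are counted independently by default
(`pipeline_params(dedup_overlap = TRUE)` counts each fragment position
once, preferring mate 2).

## Beta-binomial testing

For a unit (an editing site or a gene), the successes `k` (edited reads, or
back-splice junction reads) out of `n` trials (informative reads, or total
junction reads) are modeled as beta-binomial with mean
`logit(mu) = intercept + condition + patient` (patient as fixed-effect
indicator coding, first patient as reference) and one intraclass
correlation `rho` shared by the unit's observations.  At `rho -> 0` the
likelihood is the binomial likelihood; numerically the binomial limit is
evaluated directly below `rho = 1e-8`, where differencing log-Beta
functions loses precision.

The condition effect is tested by likelihood ratio against a chi-square
with one degree of freedom, and p-values are Benjamini-Hochberg adjusted
within each pathology.  Sites tested for a pathology are exactly those
called in all of its patients; genes enter the circRNA test only when some
compared sample has strictly more than 3 back-splice reads.  Degenerate
units (all-zero or all-`n` successes) are reported with p = 1 rather than
dropped.

**Dispersion estimation.**  A design with one mean parameter per patient
spends roughly one parameter per two observations, and the plain maximum
likelihood estimate of `rho` is then biased downward for the same reason
the ML variance is biased by (n-p)/n in ordinary regression.  In a null
simulation (10 patients, 50 trials, `rho = 0.02`, patient effects present)
that bias inflated the likelihood-ratio test's type-I error to about 0.15
at nominal 0.05.  `aluedit` therefore estimates `rho` by maximizing a
Cox-Reid adjusted profile likelihood — the profile log-likelihood at each
`rho` minus half the log-determinant of the working Fisher information of
the mean coefficients — and holds that estimate fixed in both the full and
reduced mean fits.  With the adjustment the same null simulation gives a
mean dispersion estimate of about 0.018 (true 0.02) and type-I error of
about 0.07.  The joint-ML fit remains available
(`fit_bb_regression(..., rho = NULL)`) and is used for parameter-recovery
checks.  Optimization is deterministic: BFGS from a fixed start (intercept
at the logit of the pooled rate, other coefficients 0, `rho` profiled over
a log grid by golden-section search in [1e-6, 0.9]).

## Alu Editing Index and summaries

The AEI of a sample is the coverage-weighted aggregate editing level over
adenosines of the transcribed strand inside Alu intervals: 100 times the
sum of quality-passing G-supporting reads divided by the sum of
A-plus-G-supporting reads at those positions.  Positions are assigned a
transcribed strand by majority vote of covering reads; ties and positions
with zero informative coverage contribute nothing.  By construction the
AEI equals the coverage-weighted mean of per-position editing levels.

Per-pathology tumor-normal change is summarized by the empirical CDF of
per-site differences (each site's difference is the mean across the
pathology's patients of tumor minus normal level) with two-sided paired t
and Wilcoxon signed-rank tests over sites.  Both "all test sites" and
"significant sites only" views are available, since figure-level summaries
can reasonably use either.  Editing-site burdens and global circular RNA
levels are normalized as counts per million mapped reads.

## Circular RNA stage

The circular RNA expression rate of a gene in a sample is
`BSJ / (BSJ + linear junction reads)`, consumed from junction-count tables
(CIRCexplorer2-style back-splice counts plus per-gene linear junction
counts); the package does not discover junctions.  The stage provides: the
Alu-association 2x2 Fisher exact test between genes with and without any
back-splice read; per-pathology beta-binomial tests of rate differences
(same engine and covariates as editing, with the strict >3 BSJ gate); the
Fisher overlap test of differentially edited versus differentially
circularized genes against an explicit expressed-gene universe; the
fraction of overlap genes whose differentially edited sites fall in a
flanking intron of one of the gene's circRNAs (the intron genomically
adjacent to either back-splice boundary — the narrowest reading of
"flanking"); and a two-sided Kolmogorov-Smirnov comparison of editing
deltas between genes with and without decreased circ rates.  Exonic
circRNAs only; isoform reconstruction is out of scope.

## The synthetic cohort generator

The generator emulates the structure of a paired glioma cohort: 41
patients by default, each with one tumor and one matched normal sample,
split O2 = 6, O3 = 9, A2 = 4, A3 = 5, A4 = 2, GBM = 15.  Each gene has
three exons and two introns on an alternating strand; Alu intervals
(labelled with real subfamily names) sit inside introns, half of them
carrying a 6-nt homopolymer run so that reads crossing them exercise the
homopolymer filter below its threshold.  Editing sites are planted at
intronic Alu positions whose reference base is forced to adenosine on the
transcribed strand; per-site baseline levels come from a Beta(2, 6)
hyper-prior clamped to [0.05, 0.95], and tumor samples shift the level by a
per-pathology delta clamped to [0, 1].  The editing deltas default to the
per-pathology mean tumor-normal differences reported for this design
(O2 +0.04, O3 -0.08, A2 -0.30, A3 -0.19, GBM -0.07); grade-4 IDH-mutant
astrocytoma has no reported value (it is excluded from testing with n = 2
patients), so its default (-0.12) interpolates between the neighboring
grades.  Circ-rate deltas default to the analogous reported values
(O2 -0.01, O3 -0.02, A2 -0.04, A3 -0.04, GBM -0.03; A4 -0.03).

Read simulation tiles fragments over gene bodies (pre-mRNA, so introns are
covered) under the reverse-stranded convention, draws per-sample edited
read counts as beta-binomial (a per-sample Beta draw around the true level,
then Bernoulli per read), plants germline SNPs at DNA-like fractions (0.5
heterozygous / 1.0 homozygous per patient) so that catalog exclusion is the
only mechanism that can remove them, and adds sequencing errors,
low-quality bases and the five read artifacts at configurable fractions
(defaults: 10% duplicates, 5% multi-mapped, 5% clipped, 2% indel, 2%
homopolymer-rich).  Junction tables draw per-gene depths from a Poisson
(default mean 100) and back-splice counts as beta-binomial at the sample's
true rate.  The exonic circRNA of each gene spans its middle exon, so its
flanking introns are known for the co-localization checks.  Everything is
deterministic under a fixed seed.

What the generator does *not* emulate: realistic expression-level
variation across genes, splice-aware (N-gap) alignments, fusion or
structural variation, instrument-specific error profiles, and hyper-edited
reads that fail alignment.  Passing tests therefore demonstrate the
correctness of the filter cascade, the statistics and the plumbing under
the stated generative assumptions — not robustness to every artifact of
real libraries.

## Problem sizes used by the test suite

The suite validates at sizes chosen to keep the whole run comfortably
reproducible on a laptop: caller-versus-oracle equivalence on a 4-patient
cohort (~4,600 reads per sample); truth recovery on a 4-patient,
200-site, 50-SNP cohort at 40x coverage with zero sequencing error;
test calibration on 500 null replicates and power on 200 units at 10
patients x 50 trials; the Fisher oracle on all 164,176 tables with margins
up to 30; and the pathology-contrast property (one null pathology centered,
shifted pathologies moving left) across 5 seeds at 9 patients each.
`scripts/acceptance.R` reruns the full pipeline on a seeded 9-patient
cohort and writes its headline numbers as JSON.

## Known limitations

* Patient effects are fixed, not random; with very many patients a mixed
  model would be more parsimonious, but fixed effects are the simplest
  faithful encoding of "patient as a covariate".
* The chi-square reference for the LRT is asymptotic; the Cox-Reid
  adjustment removes the dominant small-sample bias but residual
  liberality of roughly two percentage points remains at 10 patients.
* Strand assignment needs a vote majority; sites covered only by
  contradictory votes (e.g. overlapping antisense transcription) are
  dropped rather than resolved.
* The AEI here is restricted to annotated Alu intervals and majority-vote
  strands; it does not re-implement genome-wide mismatch-index variants.
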
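---
title: "Methods: methylome classification, dosage patterns, and split-read insertion calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome classification, dosage patterns, and split-read insertion calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdose)
```

# Scope

`methdose` implements the computational core of a genotype-panel analysis
for plants in which DNA methyltransferases are knocked out singly and in
combination: a wild type, a quadruple mutant lacking non-CG methylation
("ddcc"), a CG-maintenance mutant ("met1"), and a quintuple mutant with no
DNA methylation at all ("mddcc").  The package covers four analyses that
such a panel supports:

1. **Methylome profiling** — per-cytosine bisulfite calls are context-
   annotated, coverage-filtered, and summarized as coverage-weighted
   levels, windowed tracks, and a non-conversion estimate from an
   unmethylated organelle (chloroplast-like) control chromosome.
2. **Gene methylation classification** — a one-tailed binomial test
   assigns every expressed gene to one of six categories (gbM,
   Intron-teM, Other-teM, pM, dM, UM) from the wild-type methylome.
3. **Expression analysis** — FPKM filtering, negative-binomial
   differential expression, cross-genotype regulation-pattern
   classification (Redundancy, Dosage I–III, mCG, non-mCG), and a
   3′/5′ transcript-ratio test for intron-methylated genes.
4. **Transposon mobilization** — split-read detection of non-reference
   transposon insertions with target-site-duplication (TSD) calling.

Every stage is exercised end to end on synthetic data with planted ground
truth; the generator is a first-class, tested module.

# Methylome model

## Contexts and weighted levels

Plant cytosine methylation occurs in three sequence contexts — CG, CHG and
CHH, with H any base but G — maintained by distinct pathways.
`annotate_contexts()` assigns a context to every genomic cytosine on both
strands directly from the genome sequence; positions whose context cannot
be resolved (adjacent N, chromosome end) are excluded, and incoming
per-cytosine tables are validated against this map (disagreeing records
are dropped with a warning, since they indicate a stale genome build).

The level of a region is always the **weighted methylation level**

$$\bar m = \frac{\sum_i c_i}{\sum_i (c+t)_i},$$

the ratio of summed methylated calls to summed informative calls — never a
mean of per-site ratios, which over-weights shallow sites.  Regions
without informative calls are *undefined* and propagate as `NA`, never as
0, so sparse windows do not deflate profiles.

## Coverage filter and non-conversion

Cytosines with fewer than 4 informative calls are removed before any
downstream computation (`filter_coverage()`, idempotent and monotone in
the threshold).  "Coverage" means the effective C+T count of
bisulfite-informative calls, which is what per-cytosine extraction tools
report, not raw depth.  The filter is applied uniformly before *all*
downstream statistics, including the nuclear-versus-organelle comparison —
the upstream tooling this package models does not document whether that
comparison is filtered, and a single uniform rule is easier to reason
about.

Bisulfite conversion is imperfect: a fraction of unmethylated cytosines
read as methylated.  Because the organelle genome is biologically
unmethylated, its pooled weighted level estimates this non-conversion
floor (`estimate_nonconversion()`).  The defining property of a
methylation-free genotype is that its *nuclear* weighted level matches
this floor in all three contexts, within binomial sampling error.

## CG sites are kept per strand

Symmetric CG positions are not merged across strands: the per-cytosine
pipeline operates position-wise, and merging would discard the per-strand
counts the binomial tests consume.

# The binomial methylation classifier

## Regions

For every gene the classifier uses (i) the gene body (the transcribed
span), with exon-only and intron-only sub-aggregates; (ii) a 2-kb
promoter upstream of the TSS; and (iii) a 2-kb downstream region past the
TES, both strand-aware and silently truncated at chromosome ends.
Promoter and downstream regions are tiled into 500-bp bins counted from
the gene-proximal edge outward.  Promoters and downstream regions are
computed from the gene span (TSS = strand-aware span start); no
per-transcript selection is attempted, and exons of multiple transcripts
are unioned per gene.  Promoters overlapping a neighboring gene are not
trimmed.

## Tests

Counts are summed per (gene, region, context) and tested one-tailed
against a background rate: $p = P(X \ge k)$, $X \sim \mathrm{Bin}(n,
p_{bg})$.  The backgrounds are the pooled weighted levels of the
corresponding region class across all genes (bodies for the body tests,
all promoter bins for the promoter test, all downstream bins for the
downstream test), clamped to $[10^{-6}, 1-10^{-6}]$ so that synthetic
data with an exactly-zero background still yields defined tests.  For the
flank regions only the maximally methylated bin of each gene is tested
(pooled contexts), with coverage-free bins ranking lowest and ties broken
toward the gene-proximal bin; an uncovered region tests at $p = q = 1$,
i.e. untestable means "called unmethylated".

p-values are Benjamini–Hochberg adjusted **separately per (region,
context) family** across the expressed-gene set: body CG, body CHG, body
CHH, intron CHG, intron CHH, exon CHG, exon CHH, promoter pooled-C and
downstream pooled-C each form one family.  The max-bin selection is not
multiplicity-corrected beyond this gene-level adjustment.

## Decision tree

With q-threshold 0.01, in order of precedence:

1. **teM** if the body is significant in CHG *or* CHH.  teM takes
   precedence over gbM: a body with significant CG *and* CHG methylation
   is transposon-like, and the gbM definition requires non-significant
   non-CG contexts.
2. teM genes split into **Intron-teM** when the non-CG signal is
   intron-restricted — the intron-only counts are significant (against
   the body background) while the exon-only counts are not — and
   **Other-teM** otherwise.  The alternative reading, intron
   significance alone, is available as `intron_rule = "intron"`; it is
   not the default because a gene methylated across its whole body
   (intron included) would then always be absorbed into Intron-teM,
   leaving Other-teM empty by construction.
3. **gbM** if body CG is significant and body CHG and CHH are not.
4. **pM** if the best promoter bin (pooled contexts) is significant.
5. **dM** if the best downstream bin is significant *and* the promoter is
   not — so pM takes precedence over dM by definition.
6. **UM** otherwise.

The six categories partition the expressed-gene set exactly; the package
asserts this invariant on every run.

# Differential expression and dosage patterns

## The NB Wald engine

The DE engine is a deliberately transparent stand-in for a full
shrinkage-based NB framework; downstream logic consumes only
`(log2fc, padj, status)`.  Counts are normalized with median-of-ratios
size factors.  Per-feature dispersions come from a method-of-moments
estimate on within-group variability, shrunk toward a mean–dispersion
trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across all features (prior
weight 8 pseudo-observations against 4 residual degrees of freedom).  The
Wald statistic for the log fold change of group means uses the
delta-method standard error $\sqrt{(1/\mu_A + \alpha)/n_A + (1/\mu_B +
\alpha)/n_B}$ and is referred to the standard normal: the dispersion in
the denominator is pooled across thousands of features rather than
re-estimated per feature, so a small-sample t correction would be
miscalibrated (measurably conservative).  A half-count pseudocount guards
the log at zero means; all-zero features are excluded from testing.  On
negative-binomial null panels (2,000 features, 3 vs 3 replicates,
dispersion 0.1) the empirical type-I error at nominal 0.05 lands within
0.03–0.07 across seeds.

DE status uses the panel's thresholds: adjusted p < 0.01 with fold change
> 2 for genes, transposons and non-annotated transcripts, and > 4 for
antisense transcripts, applied to the Wald log2 fold-change estimate.

## Pattern classification

For every feature DE in the methylation-free genotype, the per-genotype
log2 fold changes $L$ are compared with a gap parameter `delta` (default
one log2 unit) that operationalizes "comparable" versus "further
increased" — the source analyses describe these verbally, so the numeric
rule is a package choice and is exposed as configuration.  For the up
direction: *Redundancy* when neither single-pathway mutant is DE; *mCG* /
*non_mCG* when the CG-mutant / non-CG-mutant change is within `delta` of
the quintuple-mutant change (these "comparable" rules take precedence);
*Dosage I/II* when only the CG/non-CG mutant is DE and the quintuple
mutant exceeds it by at least `delta`; *Dosage III* when both are DE and
the quintuple mutant exceeds both by `delta`; otherwise *Unclassified*.
The down direction mirrors every inequality.

## Intron-teM 3′ ratio test

Genes whose teM signal is intronic are split at the intron with the
maximal pooled non-CG weighted level into a 5′ and a 3′ part.  With
replicate-summed counts, genes with fewer than 10 wild-type 5′ reads are
excluded; the statistic

$$\log_2 \frac{(3'/5')_{\text{mutant}}}{(3'/5')_{\text{WT}}}$$

flags 3′ depletion below −1.  The ratio-of-ratios form makes the
statistic exactly invariant to rescaling both parts of one genotype
(library depth).  Zero denominators after retention yield an undefined
statistic reported unflagged with a reason code.  Summaries are emitted
per mutant, so both a quintuple-mutant-only count and an any-mutant count
are available — published descriptions of this analysis differ on which
of the two is headline (9 versus 10 flagged genes), and emitting both
sidesteps the ambiguity.

# Split-read insertion calling

The caller takes name-paired alignment records (SAM) in which junction
reads are unmapped-with-sequence or clipped, as an aligner leaves them:

1. **Candidate pairs** — at least one unmapped mate, or a discordant pair
   (not proper, insert ≥ 3 kb, or same strand).
2. **Extremity matching** — the terminal 300 bp of each annotated
   transposon (strand-normalized; families without intact extremities
   excluded; short elements contribute non-overlapping halves) are
   matched against both read orientations for the longest end-anchored
   exact match of ≥ 20 nt; equal-length matches to different elements are
   flagged ambiguous (lexicographic tie-break) and excluded from calling
   by default.
3. **Recursive genome clipping** — the non-transposon portion is searched
   in the reference by exact match; on failure one base is trimmed from
   the junction side and the search repeated until the segment would drop
   below 20 nt.  "Uniquely maps" means exactly one exact-match location
   over both strands; multi-mapping candidates are discarded.  The
   breakpoint is the junction-adjacent reference coordinate, corrected
   for trimming.
4. **Mate validation** — a candidate is kept only if its mate (a) is
   properly mapped within 3 kb on the opposite strand, (b) lies within
   the same element's extremity sequence, or (c) is itself clip-mapped to
   the same element with opposite native strand, tried in that order.
5. **Clustering and TSD calling** — breakpoints from the same extremity
   within 100 bp merge into clusters (the window is a package choice, the
   source procedure does not state one; configurable); clusters need ≥ 4
   reads.  A left-junction cluster (consensus breakpoint $b$ = end of the
   duplicated site) pairs with a right-junction cluster of the same
   element (consensus $a$ = its start) into a call when the two sides
   used opposite transposon ends and $b - a + 1 \in [4, 19]$ bp — the
   open interval "more than 3 and less than 20".  Consensus is the modal
   member breakpoint (ties toward the smaller coordinate), which is
   robust to the occasional read whose junction base coincides with the
   next extremity base.
6. **Region filters** — calls within 3 kb of a centromeric span or a
   chromosome end, within 500 bp of an N-run (≥ 4 consecutive N), or
   overlapping the donor element's own span are removed but retained in
   the output with a reason.

The alignment backend is an exact-substring index adequate for the
kilobase-to-megabase synthetic genomes the package generates; real-data
use plugs an external aligner in upstream and enters at the SAM
interface.  The algorithmic contribution — clip, recursive trim, mate
validation, cluster pairing, TSD arithmetic, filters — is independent of
the backend.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuned per test.

* **Genome** — one nuclear chromosome (margins, gene blocks with a
  promoter/exon–intron–exon/downstream footprint on alternating strands,
  a transposon zone, a 2-kb N-block centromere analogue) plus a 20-kb
  organelle control chromosome.  All coordinates are 1-based inclusive,
  matching both the GFF3 and per-cytosine table dialects.
* **Methylomes** — per-cytosine coverage is shifted Poisson (mean 20,
  minimum 1) so the ≥ 4 filter has bite.  Intergenic baselines are CG
  0.05 / CHG 0.02 / CHH 0.02; gene footprints sit at the floor except for
  planted signal: gbM bodies CG 0.3; Other-teM bodies 0.3 in all
  contexts; Intron-teM genes 0.3 in the intron only; pM/dM genes one hot
  500-bp bin at 0.4; transposon copies 0.5.  The erasure map zeroes
  non-CG in "ddcc", CG in "met1" (with non-CG mildly reduced, ×0.7,
  mirroring the secondary non-CG loss seen in CG-maintenance mutants;
  toggleable), and everything in "mddcc".  Every level is floored by a
  non-conversion rate of 0.004 — including the organelle chromosome in
  every genotype — via $p = \ell + (1-\ell)\,r$.
* **Counts** — NB counts (mean 500, dispersion 0.05, 3 replicates) with
  planted per-genotype log2 effects: Redundancy (0,0,3), Dosage I
  (0,1.5,3), Dosage II (1.5,0,3), Dosage III (1.2,1.2,3), mCG (0,3,3),
  non-mCG (3,0,3) in (ddcc, met1, mddcc) order.  The default pattern mix
  (25/35/5/5/20/10 %) follows the reported relative abundances: dosage
  regulation dominates, Dosage I is the most common form, Dosage II and
  III are rare.
* **Split counts** — intron-split genes draw 5′/3′ part counts around
  means of 100, with the 3′ mean divided by 5 in affected genotypes
  (expected statistic $-\log_2 5 \approx -2.32$) and a few genes planted
  with shallow wild-type 5′ coverage to exercise retention.
* **Read sets** — for each planted insertion the mutant haplotype is
  reference-up-to-$b$ + transposon + reference-from-$a$, giving a TSD of
  $[a, b]$.  Eight junction-spanning pairs per side (read length 100,
  staggered offsets) are emitted as unmapped-with-sequence plus a mapped
  mate, alongside background concordant pairs; decoys (TSD 3 or 20 bp,
  3-read support, masked locations) exercise the negative paths.

Everything is a pure function of (config, seed): identical seeds give
byte-identical FASTA/GFF3/TSV/SAM outputs.

What the generator does **not** emulate: sequencing error and quality
attrition, bisulfite read-level artifacts (the package starts from
per-cytosine tables), PCR duplicates, repeat-induced multi-mapping at
genome scale, transcript-assembly uncertainty for antisense and
non-annotated features (their count tables are fabricated directly), and
genome-scale chromatin organisation.  Passing recovery tests therefore
demonstrates the correctness of the statistical and algorithmic logic
under the stated noise model, not robustness to every artifact of real
libraries.

# Problem sizes and runtime choices

The validation suite runs classifier recovery on a 2,000-gene (~11 Mb)
planted methylome and a 1,000-gene all-background methylome, DE
calibration on 2,000-feature null panels, pattern recovery on 800-feature
panels, and insertion recovery on a ~175-kb toy genome with 5 planted
insertions — sizes chosen so each property is measured with comfortable
statistical resolution while the whole suite completes in minutes on one
CPU.

# Known limitations

* The DE engine is calibrated for the moderate-dispersion, few-replicate
  regime it targets; it has no outlier-count handling or independent
  filtering, and per-feature dispersion outliers are pulled toward the
  trend.
* The insertion caller's exact-match backend does not model mismatches
  within the mapped segment (only junction-side trimming); diverged or
  repetitive insertion sites require a real aligner upstream.
* The classifier inherits the max-bin construction's mild selection
  optimism for flank regions; with 4 bins per region and gene-level BH
  this is negligible at the panel's coverage, but very shallow methylomes
  would warrant a bin-level correction.
* Pattern classification conditions on hard DE status calls; features
  near the fold-change threshold can land in a neighboring pattern, which
  is why planted-panel recovery is targeted at 90%, not 100%.
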
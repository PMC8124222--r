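---
title: "Fragment-based differential methylation analysis for RRBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based differential methylation analysis for RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdmf)
```

## The analysis unit: MspI fragments

Reduced representation bisulfite sequencing (RRBS) enriches CpG-dense
genome fractions by digesting genomic DNA with MspI (which cleaves C^CGG)
and size-selecting 40-220 bp fragments before bisulfite conversion. Because
library fragments are delimited by MspI sites, the natural unit of analysis
is the *in-silico MspI fragment*: the genomic interval between two
consecutive cut sites. `rrbsdmf` reconstructs that unit computationally:

* a cut is placed one base into every `CCGG` occurrence (matching the
  enzyme's cleavage chemistry), so each internal fragment begins with `CGG`
  and ends with `C`;
* terminal pieces with only one MspI end are discarded, since real RRBS
  fragments carry MspI ends on both sides;
* size selection keeps lengths in the inclusive 40-220 bp window.

Two conventions here are declared rather than inherited from any standard:
fragment coordinates include the `CGG`/`C` overhang bases, and overlapping
`CCGG` motifs each count as cut sites (the scan allows overlaps). Both are
pinned by tests against an independent sliding-window scan.

## From per-CpG counts to fragment methylation

Input is the Bismark-coverage dialect: per-CpG lines of
`chrom, pos, pos, methylation%, count_methylated, count_unmethylated` with
1-based positions. CpG methylation is palindromic, so a call at the
reverse-strand C (the `G` position of a forward `CG`) is merged into the
forward-strand site by summing counts; calls at positions that are not part
of any CpG are dropped with a warning and tallied. Internally all
coordinates are 0-based half-open, converted once at the boundary.

A fragment's methylation level is the pooled proportion
\[
\hat m = \frac{\sum_i M_i}{\sum_i (M_i + U_i)}
\]
over all covered CpGs `i` in the fragment — not a mean of per-CpG
proportions. Pooling is the natural choice because the downstream test
operates on the pooled 2x2 count table. The coverage filter requires **at
least two distinct CpG sites each with total depth >= 10 reads**; this is
the per-CpG reading of the standard fragment-quality rule, adopted over the
alternative (>= 10 reads summed per fragment) because the per-site phrasing
is how the rule is stated wherever fragment-based RRBS analysis is
described. Raising either threshold can only shrink the passing set, a
monotonicity that is property-tested.

## Calling differentially methylated fragments

For each tissue/cell-line pair, every fragment passing the coverage filter
in *both* samples is tested on its pooled counts
\((M_1, U_1; M_2, U_2)\) with a two-sided Fisher exact test: the p-value is
the sum of hypergeometric probabilities of all tables with the observed
margins whose probability does not exceed the observed table's (with a
1e-7 relative tie tolerance so floating-point ties resolve
deterministically). A zero margin leaves a single attainable table and
returns p = 1. The implementation is authored in the package and is
verified exhaustively against a brute-force `choose()`-ratio enumeration
for all tables with margins up to 60, and spot-checked against
`stats::fisher.test`.

A fragment is a **DMF** when

* `p <= alpha / n_tests` with `alpha = 0.01` (Bonferroni), where `n_tests`
  is the number of fragments actually tested in that comparison — the only
  defensible family, since each pairwise comparison has its own testable
  set; and
* the absolute difference of pooled levels is at least 0.25 (inclusive).

The two filters commute; both marginal sets can be inspected in the output.
By convention sample B is the cell line, so `diff > 0` means
*hypermethylated in the cell line*.

**Common DMFs** are fragments significant in every pair, matched by exact
coordinates (all samples share one catalogue, so identity — not overlap —
is well defined). Direction concordance is `both_hyper`, `both_hypo`, or
`discordant`; summary percentages use half-up rounding to one decimal, the
convention used when such partitions are reported.

## Genomic context

* **Promoter**: 2 kb upstream to 1 kb downstream of the TSS, strand-aware
  (`[tss-2000, tss+1000)` on `+`, mirrored to `[tss-999, tss+2001)` on
  `-`), clipped at contig bounds.
* **Gene context** precedence: promoter > junction > exon > intron >
  intergenic, with any-overlap (>= 1 bp) assignment. `junction` means the
  fragment overlaps both exonic and intronic sequence of one gene, i.e.
  spans an exon-intron boundary; it outranks its parts because it is
  reported as a separate, mutually exclusive category. Intergenic is the
  complement: neither promoter nor within any gene span. Assigned-gene ties
  break by smallest TSS distance, then lexicographic name. Since fragments
  are <= 220 bp, containment and overlap rules are nearly equivalent; the
  any-overlap rule is the simplest testable one.
* **CGI context**: core (overlaps a merged CpG island) > shore (within
  2 kb flanks) > shelf (2-4 kb flanks) > open sea. The 2 kb / 2-4 kb widths
  are the community convention; the terms themselves do not fix widths.

Both context classifications partition every fragment set — pie-chart
proportions always sum to 100% — and this is asserted as an invariant.

Gene-set enrichment of DMF-associated genes uses the one-sided
hypergeometric tail `P(X >= overlap)` with the background defined as the
genes overlapping commonly analysed fragments, and Benjamini-Hochberg
adjustment across sets (the convention of the enrichment services this
replaces; the family of sets is not a confirmatory family, so FWER control
would be miscalibrated here).

## Global summaries

Level histograms use 50 equal bins on [0,1] (left-closed, last bin
right-closed, so counts are conserved); pairwise sample similarity is
Pearson's r over fragments passing the filter in both samples; sample
clustering is agglomerative with distance `1 - r` and average linkage on
fragments common to all samples — a declared, seed-free choice, since
"hierarchical clustering" alone does not fix a metric or linkage. Columns
enter in sample-name order, which makes tie-breaking deterministic.
Element-wise tissue-vs-cell-line comparisons use the two-sided Wilcoxon
rank-sum test (`stats::wilcox.test`: exact for small untied samples, else
the tie-corrected normal approximation with continuity correction; the
small-sample exact path is verified against exhaustive rank enumeration).
Report medians are printed to two decimals; TSVs keep full precision.

## The synthetic data generator

Real paired tumour/cell-line RRBS data cannot be bundled, so the package
ships a seeded generator whose defaults *are* the study conditions used in
all validation:

| parameter | default | meaning |
|---|---|---|
| `n_contigs` x `fragments_per_contig` | 20 x 100 | 2,000 size-selected fragments |
| `frac_short`, `frac_long` | 0.08 each | out-of-window fragments exercising size selection |
| `cpg_range` | 3-8 | CpGs per fragment |
| `beta_mixture` | (1.5, 15, 15, 1.5, 0.45) | bimodal true methylation: low mode mean 0.09, high mode mean 0.91, 45% high |
| `coverage_mean`, `coverage_dispersion` | 30, 5 | negative-binomial per-CpG depth |
| `n_planted_dmf` | 200 | planted DMFs, all shared across pairs |
| `planted_delta` | 0.5 | true methylation shift at planted fragments |
| `planted_hyper_fraction` | 0.88 | planted DMFs shifted upward in the cell line, echoing the ~88% direction skew seen in tumour-vs-cell-line comparisons |
| `n_pairs` | 2 | tissue/cell-line pairs |

Contigs are assembled as `pad CCGG inner1 CCGG inner2 ... CCGG pad` with
A/T-only background, so digestion recovers exactly the planned fragments
and every C belongs to a planted CpG — CpG counts per fragment are exact by
construction. The Beta-mixture fragment level, negative-binomial coverage
(overdispersed, with Poisson as the `size -> infinity` limit) and binomial
methylated counts give the bimodal level histograms characteristic of RRBS
methylomes. No coverage distribution is published for the libraries this
emulates; the negative-binomial parameters are a modelling choice. CpGs
within a fragment share one true level because the fragment is the analysis
unit; intra-fragment homogeneity is the simplest structure that exercises
pooling.

The cell-line sample equals the tissue sample except at planted fragments,
shifted by `planted_delta` in the planted direction. For a hypermethylated
planted fragment the tissue level is drawn from the low mode truncated at
`1 - planted_delta` (mirrored for hypomethylated ones), so the true
difference is exactly `planted_delta` and clipping never occurs under the
defaults; the clip-and-record path remains for extreme configurations.
Planted fragments are chosen only among fragments with >= 2 CpGs, so
sensitivity estimates are not confounded by the coverage filter.

What the generator does **not** emulate: raw reads, alignment error,
incomplete bisulfite conversion, non-CpG methylation, per-CpG
heterogeneity within fragments, and biological covariance structure across
samples. Passing tests therefore demonstrate correctness of the pipeline's
logic and calibration of its statistics under a clean generative model —
not performance on real libraries.

An interesting emergent property: shifting only 10% of fragments upward
moves the *median* methylation by ~0.3, because the bimodal distribution
puts the median on the thin trough between modes. Small planted fractions
can therefore reproduce the ~10% global median hypermethylation seen in
cell lines relative to their source tissue.

## Validation scale and numerical choices

Validation uses problem sizes chosen to exercise every code path while
keeping a full run in minutes: the standard fixture above for recovery
(sensitivity >= 90%, direction agreement >= 99%, and no calls outside the
planted set in >= 95% of 50 replicate count draws), 200 null replicates for
family-wise error control (the observed rate is far below the nominal 0.01
because Fisher's test is conservative on discrete tables), the exhaustive
Fisher sweep to margins of 60, and 1,000 random 10 kb sequences for the
digestion oracle. All randomness flows from one seed through fixed
per-stage substreams, so every artifact is bit-reproducible; replicate
count data reuse a fixed genome catalogue and vary only the count seed.

Degenerate inputs are handled by explicit convention rather than error
where a convention exists (zero-margin Fisher tables give p = 1; empty DMF
intersections give empty tables; an empty concordance summary is all
zeros), and by informative errors where none does (undefined methylation
level at zero depth, zero-variance samples in correlation/clustering,
malformed coverage lines with their line number).

## Known limitations

* Bonferroni is the only multiplicity correction offered for DMF calling
  (by design — it is the procedure this pipeline codifies); no FDR or
  dispersion-aware (beta-binomial) models.
* Common-DMF matching requires a shared catalogue; cross-genome or
  overlap-based matching is out of scope.
* The junction category requires exon and intron overlap of the *same*
  gene; nested or antisense gene structures may classify differently than
  visual inspection would suggest.
* With more than two pairs, concordance labels derive from the first two
  comparisons; additional pairs only restrict membership.
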
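---
title: "Methods: cohort-level absolute CNV and cn-LOH quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level absolute CNV and cn-LOH quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcohort)
```

## The problem

Allele-specific copy-number callers (ASCAT for SNP arrays, Sequenza for
paired tumour/normal sequencing) emit, per sample, a set of
non-overlapping genomic segments with the integer copy number of each
parental allele, `n_major >= n_minor >= 0`. Each caller looks at one
sample at a time. The questions a cohort study actually asks — which
regions are recurrently gained or lost, at what absolute magnitude,
where copy-neutral LOH concentrates, which samples share aberration
patterns — require aggregating those per-sample calls across the whole
cohort without collapsing absolute copy numbers into a lossy
gain/loss dichotomy. `cnvcohort` does that aggregation: it is a
re-usable computational core for cohort-level absolute CNV and cn-LOH
quantification, with text tables as the primary output and plots as a
thin rendering of those tables.

All internal coordinates are 0-based half-open; the ASCAT/Sequenza
readers convert from their 1-based inclusive conventions at parse time
so interval arithmetic never carries off-by-one cases.

## Windowed copy-number matrices

The genome of a build (bundled hg18/hg19 descriptors, or a custom
chromosome-sizes + centromere pair) is tiled from position 0 with
windows of length `L` (default 2 Mb, or a percentage of each
chromosome's length, rounded down to whole bp per chromosome). Windows
never overlap a centromere: a straddling window is replaced by its two
arm pieces, and any piece shorter than `L/2` — including the
chromosome-terminal remainder, which we treat by the same rule for
uniformity — is merged into its nearest contiguous neighbour on the
same arm, so windows stay of comparable size. When a short piece has
neighbours on both sides it merges upstream (lower coordinate); the
rule is fixed purely so output is deterministic. An entire arm shorter
than `L/2` still yields one window, so no covered arm silently
disappears.

For each sample `A` and window `W`, every base of `W` receives a copy
number: the covering call's total where one exists, otherwise a fill
value. The matrix entry is the length-weighted mean over the window,
rounded to the nearest integer. Rounding is half-away-from-zero
everywhere in the package (2.5 becomes 3, −2.5 becomes −3): plain
"nearest integer" leaves the .5 case open, and this choice treats gains
and losses symmetrically. The fill is the sample's ploidy for the main
matrix `M`, so uncovered stretches are presumed unremarkable rather
than deleted.

The relative matrix `M'` subtracts each sample's ploidy from its
entries: 0 means no net change, the lower bound is −ploidy (so −3/−4
can only occur for samples of ploidy ≥ 3/≥ 4), and values are clamped
to [−4, +6] to keep the category scale readable. Storage keeps the full
−4..+6 range; for display and for region comparison, gains of +4..+6
pool into a single "≥ +4" bin. With a non-integer (tie-averaged) ploidy
the subtraction happens on the rational value and is then rounded by
the same rule, so categories stay integral.

## Ploidy estimation

A sample's ploidy is estimated as the modal value of a coarse windowed
matrix built with windows of 10% of each chromosome's length and a
fixed fill of 2 for uncovered bases (at that window size the fill
rarely dominates a window). Windows of all chromosomes are pooled —
including sex chromosomes, since nothing in the windowing distinguishes
them; a user who wants them excluded can filter the input. If several
values tie for the highest frequency the estimate is their arithmetic
mean, which can be non-integer (an exact 50/50 diploid/triploid genome
gives 2.5). User-supplied ploidies, per sample or one constant for all,
take precedence over the estimate sample by sample.

Two properties are worth knowing. The estimator is invariant to
segment fragmentation (splitting calls without changing values moves no
window mean). And it has a documented failure mode: events whose
absolute copy number equals the fill value 2 compete with it — in a
haploid genome, recurrent +1 gains plus a large coverage gap can tie or
outvote the true mode (the test suite pins an exact 1.5 tie built this
way). Whole-arm events covering most of a genome shift the mode too,
by construction: the mode is the baseline only while it keeps a
plurality of windows.

## The base-resolution segment matrix and event classes

Windowing trades resolution for regularity. For frequency tracks the
package instead partitions each chromosome at the union of *all*
samples' segment breakpoints. Every resulting piece is covered either
fully or not at all by any input call, so each call is split across the
pieces it covers with its allele counts copied verbatim, and a sample
without a call at a piece is simply absent — no fill is ever invented
at base resolution. Adjacent pieces whose full set of per-sample cells
is identical are coalesced afterwards; the merge never bridges an
uncovered gap and provably changes no frequency. Partitioning an
already-partitioned set returns the same partition.

Each (sample, segment) cell is classified against the sample ploidy
`p`:

* **state**: gain / neutral / loss by comparing the total to
  `round(p)` — "neutral" means the copy number equals the ploidy;
* **LOH**: the minor allele has zero copies while at least one copy is
  retained;
* **cn-LOH**: LOH whose retained allele has exactly `round(p)` copies —
  no net change, one parental allele lost (uniparental disomy being the
  classic case);
* **zygosity**: homozygous if either allele has zero copies, else
  heterozygous.

A homozygous total deletion (0,0) is classified as a homozygous loss
but *not* LOH: with no retained allele there is no allelic imbalance to
speak of. cn-LOH is a subset of LOH by construction. With a
tie-averaged non-integer ploidy, the integer comparisons use
`round(p)`; note the relative category still rounds `total − p`, so a
2.5-ploidy sample at total 3 is "neutral" in state but +1 in category —
a knowingly tolerated edge of the tie rule, confined to tie-averaged
samples.

## Frequency tracks

For every segment of the partition (or every window, when full
resolution is disabled) and every relative category −4..+6, the stacked
table reports `100 × carriers / N` with the explicit carrier list. The
denominator is always the full cohort size `N`: a sample with no call
at a segment counts in no category rather than shrinking the
denominator, which keeps percentages comparable along the genome. The
neutral share is computed but left out of the stacked plot by default
(it is implicit as the remainder). cn-LOH and LOH percentages are
reported per segment as line tracks with negated values, following the
convention of drawing them in negative ordinates; the het/hom table
crosses zygosity with state the same way, losses negative. Every plot
has a text twin carrying strictly more information than the figure.

## Clustering and heatmaps

Sample dendrograms and heatmaps cluster the windowed matrix (absolute
values by default, ploidy-relative on request; the two give identical
trees when every sample shares one ploidy). Distances are Euclidean and
the agglomeration is `hclust`'s "ward.D" — Ward's update applied to
unsquared dissimilarities — both user-overridable; the defaults are kept
because they are the established behaviour this kind of analysis
reports. The test suite checks the implementation against a hand-coded
O(n³) Lance–Williams agglomeration oracle, exact in topology and merge
heights. Heatmap columns stay in genomic order unless window clustering
is requested; with a sample-annotation table, one decorated
dendrogram/heatmap per feature column is produced. Dendrograms export
to Newick with merge heights as branch lengths.

## Region comparison

To compare the gain-category mix of two regions (the motivating case:
two chromosome arms with similar total gain frequency but different
magnitude spectra), each sample is assigned one category per region —
the length-weighted mode over the region of its display bins, with
uncovered bases counting as "no gain" and mode ties resolving to the
higher bin; a "maximum touched category" alternative is available by
flag. The resulting categories × regions table goes to a two-sided
Fisher exact test: 2×2 tables are always exact (hypergeometric sum of
outcomes no more probable than observed — the common two-sided
convention, stated here because conventions differ); r×2 tables are
exact up to a grand total of 200 and Monte-Carlo with a reported
replicate count beyond. The suite verifies the p-values against
exhaustive same-margin enumeration.

## The synthetic-cohort generator

All validation runs on generated cohorts with known truth, because real
cohorts have none. A cohort spec fixes the sample count, per-sample
baseline ploidies, planted events (interval, type gain/loss/cn-LOH,
ploidy-relative magnitude, carrier fraction), a coverage-gap rate and a
fragmentation rate; generation is a pure function of the seed. Baseline
genomes carry `(ceiling(p/2), floor(p/2))` alleles; gains add copies to
the major allele, losses remove from the minor allele first, cn-LOH
sets `(round(p), 0)`. Carriers are the next `round(fraction × n)`
samples of a per-group seeded shuffle, so planted frequencies are exact
and several categories can share one interval with disjoint carriers.
Gaps are one uniformly-placed interval per chromosome; fragmentation
splits segments without changing values.

The generator emulates segment-level structure only: it plants no
caller noise, no subclonal (non-integer) states, no allele-split
ambiguity, and its gaps are contiguous rather than scattered. Passing
tests therefore demonstrate correctness of the aggregation machinery on
clean calls, not robustness to caller error — by design, since the
upstream callers own that problem.

The bundled `hcc_like_spec()` preset is a 96-sample liver-cancer-like
cohort on hg19: both the 1q and 8q arms gained in 54/96 samples but
with different category mixes (">= +4" in exactly 7/96 on 1q versus
24/96 on 8q), an 8p loss in 24/96, 17p cn-LOH in 14/96, and a third of
the cohort tetraploid. The carrier counts echo the arm-level contrast
reported for hepatocellular carcinoma cohorts (about 7% versus 25%
strong gains at comparable total gain frequency); the preset is
synthetic and noise-free so every planted percentage is recovered
exactly.

## Problem sizes and numerical choices

The validation suite sizes its random cohorts so that brute-force
per-base oracles stay exhaustive: 100 cohorts of up to 5 samples on two
chromosomes of 150–350 kb for the segment-matrix and windowed-matrix
oracles (windows of 50/100 kb), 50 cohorts for ploidy recovery, 200
random matrices of up to 8 samples for the clustering oracle, and 500
random tables of total ≤ 40 for the Fisher oracle — sizes at which the
oracles enumerate every base, table or merge exactly. The end-to-end
determinism check runs the full 96-sample preset twice and compares
every text output byte for byte.

Fixed numerical conventions, collected in one place: rounding is half
away from zero; relative values clamp to [−4, +6]; the GISTIC export
floors a total copy number of 0 at 0.1 before `log2(cn/2)` and uses a
marker-count surrogate of segment length / 10 kb (min 5) since segment
tables carry no probe counts; window merge ties cannot occur (a piece
has at most one upstream neighbour); mode ties average (ploidy) or
promote to the higher bin (region categories); Fisher two-sided
comparisons use the standard 1e-7 relative tolerance when comparing
table probabilities.

## Known limitations

* Intra-tumour heterogeneity is out of scope: copy numbers are integral
  per cell population, and subclonal mixtures are not modelled.
* No built-in two-group comparison; generate the tracks per group and
  compare, or use the region test on explicit intervals.
* The ploidy estimator's fill-value collision described above.
* Cytoband names are not bundled; regions are explicit
  `chrom:start-end` intervals (band tables vary by source, and
  bundling one would freeze a choice better left to the user).
* GISTIC itself is never run; only its input file is produced.
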
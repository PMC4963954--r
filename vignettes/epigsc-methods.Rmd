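---
title: "Methods: chromatin state, signal clustering and cross-platform methylation in epigsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin state, signal clustering and cross-platform methylation in epigsc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigsc)
library(dplyr)
```

`epigsc` analyses the regulatory epigenome of germline stem cells from
four kinds of tabular input: peak intervals (BED), binned coverage
tracks (bedGraph), per-CpG bisulfite counts (TSV) and expression
tables (TSV). This vignette explains the statistical procedures, the
parameters that matter, the synthetic-data model used to validate the
pipeline, and the numerical conventions — in enough detail that a
reader can judge what a passing test does and does not establish.

## Coordinate and data conventions

All coordinates are 0-based, half-open (the BED convention),
everywhere. The one 1-based input — the position column of bisulfite
count tables, as emitted by common callers — is converted at the
reader boundary (`read_bisulfite()`), so no other function ever
reasons about coordinate origins. Two intervals overlap iff they share
a chromosome and their half-open ranges intersect; intervals that only
abut do not overlap. A peak's *center* is the floor of its coordinate
midpoint. Overlap and nearest queries are served by
GenomicRanges/IRanges behind the tidy interfaces; the test suite
cross-checks them against a brute-force all-pairs scan.

The promoter is the strand-aware window `[TSS − 2000, TSS + 500)` —
2500 bp exactly — adopted globally for bivalent calling, peak-promoter
fractions and methylation windows, since a single promoter definition
removes a whole class of inconsistencies between analyses. TSS
distances are signed relative to gene orientation (negative =
upstream); an `signed = FALSE` switch yields absolute distances for
users who prefer the unsigned convention. Nearest-gene ties are broken
by smaller absolute distance, then lexicographically smaller gene id,
so results are reproducible across platforms and input orderings.

## Enhancer and promoter chromatin state

Candidate enhancers are H3K4me1 peaks. By default, candidates whose
center lies within 2 kb of a TSS are excluded, because TSS-proximal
H3K4me1 mostly reflects promoter chromatin; the exclusion is a flag
(`exclude_promoter_proximal`) and both behaviours are tested. A
candidate is **active** when at least 1 bp of an H3K27ac peak overlaps
it, **poised** otherwise; a `min_overlap_frac` option tightens the
overlap requirement for users who consider single-base overlaps too
permissive. Each call carries its nearest gene within 200 kb (single
nearest gene) and its signed TSS distance.

A gene is **bivalent** when both an H3K4me3 peak and an H3K27me3 peak
overlap its promoter. Bivalent counts are monotone under peak-set
shrinkage — a property the suite verifies on subsampled peak sets —
which is the behaviour one should demand of any any-overlap rule.

## Track normalization and K-means signal classes

Coverage tracks carry 50-bp bins normalized to RPKM:

$$\mathrm{RPKM} = \frac{\text{count}}{(\text{bin width}/1000) \cdot (\text{library size}/10^6)}.$$

For clustering, tracks are (1) smoothed with a rectangular mean kernel
of half-width 1 bin (150 bp effective window; the half-width is a
parameter, and edges use the truncated mean so constants are preserved
exactly), (2) square-root transformed to damp noise and outliers, and
(3) cut into a regions × positions matrix spanning ±5 kb around each
peak center (200 columns at 50-bp bins), zero-filled beyond chromosome
ends. Matrices from several marks/cell types (typically H3K4me1 and
H3K27ac in each of two cell types) are concatenated column-wise and
partitioned with K-means.

K-means uses seeded k-means++ initialization and Lloyd iterations
(Euclidean distance, ≤ 300 iterations, stop when total centroid
movement < 10⁻⁶), with 10 restarts keeping the lowest-inertia
solution — restarts are what make a fixed-seed result also a *good*
result rather than a single local optimum. The iteration-wise inertia
trace is retained and asserted non-increasing. Empty clusters are
re-seeded with the point farthest from its centroid. Class labels are
renumbered by descending centroid mean, so "class 1" is always the
strongest-signal class regardless of initialization. K defaults to 4
for enhancer signal and 3 for promoter methylation, both configurable.
Rows and columns are *not* standardized before clustering — only blur
and square root are applied — which users should keep in mind if they
feed matrices with wildly different scales per track.

## DNA methylation: two assays, two scores

Capture assays (MethylCap/MeDIP) measure enrichment, which grows with
both methylation and local CpG density. The package scores a window by
the **relative methylation score**

$$\mathrm{rms} = \frac{\text{window RPKM}}{\#\text{CpGs in window}},$$

a deliberately simple, monotone normalization: every downstream
consumer (clustering, calling, correlation) is monotone in the score,
so a monotone surrogate preserves the analysis semantics without
re-implementing a full coupling-factor model. Windows with zero CpGs
carry no interpretable capture signal and are flagged `no_data`.

Capture **calling** compares the capture library to its matched input
library per window: under no enrichment, the capture count among
`capture + input` reads is Binomial with success probability equal to
the capture library's share of the summed depths. The one-sided exact
binomial tail is BH-adjusted across windows, fold change is computed
on pseudocounted (pseudocount 1), depth-normalized counts, and a
window is `highly_methylated` iff q < 0.01 **and** fold > 2. The
comparator is the input library rather than a genome-background rate
because a matched input is the natural null for an enrichment assay.

Bisulfite assays are scored by the **absolute methylation signal**,
the pooled ratio ams = ΣC / Σ(C+T) over in-window CpGs (per-site
averaging is available as an option; pooling makes the score invariant
to how counts are split across duplicate site records). Windows with
summed coverage below 10 — a customary bisulfite coverage floor — are
`no_data`. Calling runs two one-sided exact binomial families on the
pooled counts, against p₀ = 0.25 and p₀ = 0.75, *each BH-adjusted
separately* across all covered windows (two stated criteria, two
families); `highly_methylated` requires the 0.75-family at q < 0.01,
`methylated` the 0.25-family. The exact tail is verified in the suite
against brute-force pmf summation for every (n ≤ 25, C) pair at both
nulls, to 10⁻¹².

**Cross-platform comparison.** Promoter windows (five 500-bp windows
per promoter) are scored in both assays; Pearson correlation is
computed over windows where both assays have data (the count of paired
windows is always reported, and a `covered_only = FALSE` mode keeps
all scored pairs). Degenerate inputs — fewer than 3 pairs, or a
constant score vector — raise errors rather than returning NaN.
Per-gene promoter calls use the permissive any-window rule; two
samples are then partitioned into a-specific / b-specific / shared
methylated promoters. Gene bodies are called over 1-kb tiles with the
TSS-side 500 bp excluded, because that strip lies inside the promoter
window and would otherwise make every promoter call imply a body call.
The three-way gene categorization gives promoter methylation
precedence: promoter-methylated (with or without body), body-only,
hypomethylated.

## Expression statistics

The paired Wilcoxon signed-rank test drops zero differences, ranks
|differences| with midranks, and computes the exact null distribution
of the positive-rank sum for n ≤ 25 by convolution over the (possibly
tied) rank multiset — algebraically identical to enumerating all 2ⁿ
sign assignments, which is precisely how the test suite's oracle
checks it. Above n = 25 a normal approximation with tie-corrected
variance and continuity correction takes over; the two branches agree
to within 0.01 at the cutover on random data. Two-sided p-values are
`min(1, 2·min(lower, upper))`.

Differential expression between two single libraries (control vs
knockdown) uses the exact two-sided binomial test of the per-gene
count split against the library-share proportion, BH-adjusted, with
direction from pseudocounted, depth-normalized fold change. This is a
replicate-free test by construction: it measures whether a gene's
count split is inconsistent with the global depth ratio, and its
type-I error is verified on null simulations. Replicate-aware testing
(DESeq2-style dispersion estimation) is deliberately out of scope.

## The synthetic-data model

`simulate_genome()` lays out genes, enhancers (four planted classes:
shared, FGSC-specific, ESC-specific, weak), transposable-element loci
of six families and imprinted-like DMRs on disjoint, shuffled slots of
one 10-Mb synthetic chromosome. Slotting guarantees non-overlapping
gene bodies, distal enhancers, and promoters that can never collide —
deliberate simplifications that keep planted truth unambiguous. CpG
sites are sparse in background (~1 per 150 bp) and dense in islands
(10 bp), promoters (25 bp), TE loci (50 bp), DMRs (20 bp) and
methylated gene bodies (40 bp); density is co-located with plantable
regions so that every scored window carries CpG-borne signal. CpG
islands sit at 60 % of promoters and inside half the TE loci.

ChIP tracks draw per-bin counts from a negative binomial (variance
μ + 0.05·μ², dispersion exposed) with 20-fold elevated mean inside
planted peaks and an expected library of 10⁶ reads. The capture assay
draws per-bin counts proportional to the number of methylated CpGs in
the bin over a uniform background, with a matched uniform input
library; bisulfite coverage is Poisson(30) per CpG with beta-binomial
methylation around 0.8 (methylated) and 0.05 (unmethylated),
concentration 10. Promoter methylation is planted in 30 % of FGSC
promoters; half of those are shared with MGSCs, and 15 % of the
remainder are MGSC-only, yielding female-only / male-only / both /
neither labels per gene. Bodies are methylated in 90 % of
promoter-methylated genes (and 10 % of others). Bivalency is planted
in 10 % of FGSC and 25 % of ESC promoters — bivalent domains are less
prevalent in germline stem cells than in ESCs. TE families carry
opposite-sex frequency biases (0.8 vs 0.3). Expression is log-normal
FPKM with a 4-fold median suppression for promoter-methylated genes, a
4-fold boost for genes nearest cell-type-specific active enhancers,
and ≥ 2-fold planted up-regulation for 50 knockdown-responsive genes;
counts are Poisson around FPKM. Every assay consumes its own derived
RNG stream, so the whole study is bit-reproducible from one seed.

What the generator does **not** emulate: read-level artifacts
(mappability, GC bias, fragment-size effects), overlapping or nested
genes, chromatin-state gradations between "peak" and "background",
incomplete bisulfite conversion, and copy-number structure. Recovery
rates near 1.0 on this model therefore demonstrate that the
*inference machinery* is correct under its stated noise model — not
that real FGSC data would be called with that accuracy.

## Problem sizes and runtime choices

The validation suite runs the full default study (10-Mb chromosome,
500 genes, 400 enhancers, 10⁶-read libraries, seed 17) for the
recovery checks, a 3-Mb / 100-gene configuration for pipeline and
generator unit tests, 10 000 windows for the latent-correlation check
and 10 000 genes for the null type-I check — sizes chosen so the
planted effects dominate sampling noise while the whole suite stays
fast on one CPU. The end-to-end `run_pipeline()` determinism check
runs the default study twice and compares `summary.json` byte for
byte.

## Design choices and limitations

* The package's interface is its functions, `run_pipeline()` and this
  vignette; no shell entry point is shipped, since the intended user
  drives analyses from R.
* Cross-cell-type "specific" enhancer sets come from clustering; naive
  set subtraction is easy to assemble from `classify_enhancers()`
  output for sanity checks but is not the primary path.
* The FDR procedure is Benjamini–Hochberg throughout (the default of
  the methylation tooling ecosystem); the two bisulfite families are
  adjusted separately.
* `run_pipeline()` caches each stage on an md5 digest of its inputs
  plus the relevant config; rerunning unchanged is a no-op, and
  deleting one stage's output recomputes exactly that stage. The cache
  is per-output-directory, not content-addressed across runs.
* Not implemented, by design: GO/phenotype enrichment (gene lists and
  per-class BED are exported for external tools), read alignment and
  peak calling (peaks are inputs), MEDIPS/MethylKit bit-compatibility,
  bisulfite conversion-rate estimation, FPKM computation from raw
  reads, and replicate-aware differential expression.
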
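---
title: "Methods: signal-inducible super-enhancer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-inducible super-enhancer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`SEdynamics`, the parameters that matter, the numerical decisions taken
where the underlying methods leave room, and what the synthetic-data
tests do and do not demonstrate.

## Coordinates and overlap semantics

All on-disk formats follow their native conventions (BED family and
bedGraph 0-based half-open; GTF 1-based closed); in memory everything is
a `GRanges` (1-based closed), converted at the I/O boundary. Overlap
always means at least one shared base — half-open adjacency in BED
coordinates is *not* overlap, matching `bedtools intersect` defaults —
and every overlap, merge and distance operation ignores strand, because
enhancer calls are unstranded. Chromosome names are matched as exact
strings; `check_chrom_names()` warns when two inputs share no naming
scheme rather than silently renaming, since a stray `chr` prefix
usually indicates a data error worth surfacing.

Gene–SE distance is edge-to-edge between gene body and SE span
(`bedtools closest` semantics), not TSS-anchored: the 50 kb link window
is conventionally applied to region boundaries, and an anchor choice
would silently change which genes are called SE targets. Ties produce
multiple links so downstream gene sets do not depend on input order.

## Super-enhancer calling

The calling pipeline for one condition is: remove blacklist-overlapping
peaks; drop peaks overlapping ±`tss_flank` (default 2,000 bp) of any TSS
(gene start on `+`, gene end on `-`); stitch the survivors, merging
peaks within `stitch_distance` (default 12,500 bp) transitively; score
each stitched span; split SE from TE at the tangent point.

Signal is quantified as reads per million mapped reads per base pair
(rpm/bp): mean per-base coverage over the stitched span divided by
(library size / 10⁶). Coverage tracks are consumed as piecewise-constant
bedGraph already extended to fragment size (200 bp) by their producer;
this keeps the package free of BAM handling and makes the extension an
explicit contract of the track, not a hidden step. Net density is
`max(signal − input, 0)` — input can exceed signal in noise regions, and
negative densities would corrupt the ranking. The density denominator is
the full stitched span (gaps included); scoring only constituent bases
would be the main alternative and would scale all densities upward
without changing the ranking much, but the span convention matches how
ranked-density curves are usually drawn.

**Tangent cutoff.** Densities are sorted ascending; ranks are rescaled
to [0, 1] by (n−1) and densities to [0, 1] by (max−min). The cutoff is
the density at which the slope of the scaled curve first reaches 1
scanning from the low end — the point where a slope-1 line is tangent to
the curve. The discrete derivative is a centred 3-point difference after
a running-mean smoother of `max(1, n/100)` ranks; without smoothing, a
plateau of tied densities produces a jagged derivative and an unstable
crossing. Two properties anchor this scheme: densities sampled from
y = x² must yield a scaled cutoff of 0.25 (the analytic tangent point of
a slope-1 line), and a two-regime step curve must classify exactly the
high regime as SEs. Ties at the cutoff go to the TE side (SE requires
strictly greater density), which keeps SE calls conservative. Degenerate
inputs — fewer than three regions, or all densities equal — yield no
cutoff and an all-TE partition rather than an arbitrary split. Because
both axes are rescaled, the partition is invariant to multiplying all
densities by a constant, so library-size errors cannot change SE calls.

## Binding dynamics and SE patterns

Sites are labelled by comparing the two condition peak sets with ≥1 bp
overlap and no reciprocal-fraction threshold (the default `bedtools
intersect` criterion). A persistent site is represented in each
condition by that condition's own peak coordinates, with partner indices
recorded; inventing merged coordinates would make SE-overlap counts
depend on an arbitrary fusion rule. A before-peak overlapping several
after-peaks yields one persistent label with all partners, preserving
the partition identity |PRIMARY| + |PERSISTENT| = |before peaks|.

Each SE is then classified by the labels it overlaps (SE1/SE2/SE3 after
stimulation for persistent-only / both / secondary-only; SE4/SE5/SE6
before, with primary in place of secondary). An SE overlapping no
labelled site is explicitly `UNBOUND`, which matters when SEs are called
from one mark (e.g., open chromatin) and labelled with another TF's
sites. Transitions track each before-SE's overlapping after-SEs: `lost`
when none, `persists_as` when the after pattern is the expected
continuation (SE4→SE1, SE5→SE1/SE2, SE6→SE3), `reclassified_as`
otherwise; multi-mapping is flagged rather than resolved.

## Permutation enrichment

The observed statistic is the number of query features (SNPs are 1 bp
intervals) overlapping the region set, counted once per feature and
normalised per 10 Mb of region-set size (`raw / region_bp × 10⁷`), so
region classes of very different total size are comparable. The null
re-places each region independently, width preserved, uniformly over
every genome position where it fits within a chromosome and overlaps
neither the blacklist nor the original region set; chromosomes are
implicitly weighted by their count of valid placements, and randomised
regions may overlap one another (independent placement). Randomisation
is genome-wide rather than within-chromosome; with chromosome choice
proportional to valid positions the two coincide in expectation for
size-homogeneous genomes, and genome-wide is the less constrained null.
Both conventions in common use are reported: the z-score
(obs − null mean)/null sd with 1.96 as the two-sided 5% line, and the
one-sided empirical p `(1 + #{perm ≥ obs})/(1 + n_perm)`. A constant
null (fully constrained placement) is flagged `degenerate_null` with
z = ±∞ by the sign of the departure, or 0 when the observation equals
the constant. Per-pattern tables apply no cross-pattern correction to
the primary columns — the classes are few and hypotheses pre-specified —
but a Bonferroni column is emitted alongside. Internally the null loop
runs on pre-computed placement gaps with plain integer arithmetic;
`GRanges` appear only at the API boundary, which keeps 1,000
permutations per class inexpensive.

## Expression statistics

CPM is computed via `edgeR::cpm` (columns sum to 10⁶) and genes are
retained when CPM > 0.5 in at least `min_samples` = 2 samples. The
built-in DE test is a deliberately transparent stand-in for a full
linear-model fit: log2(CPM + 0.5) — the pseudocount avoids −∞ at zero
counts — with group-mean log2FC and a per-gene two-sided Welch t-test.
Zero within-group variance makes t undefined; those genes are resolved
directly (p = 1 with no difference, p = 0 with perfect separation).
Significance flags recompute from the conventional thresholds (p < 0.05
and |log2FC| ≥ 1; average log2 expression > 5 for high expression) and
`de_flags()` applies the same rules to any externally supplied DE table,
which is the recommended route when a moderated fit is available.

Group comparisons use `stats::kruskal.test` followed by Dunn's pairwise
z on the pooled ranks with the tie-corrected variance
σ² = N(N+1)/12 − Σ(t³−t)/(12(N−1)), average ranks for ties, and
Bonferroni over all pairs; an all-tied input returns p = 1 throughout
rather than NaN. "Regulatory effect" in the group comparison is
|log2FC|, the only stated effect measure, grouped by a gene's regulatory
pattern with mutually exclusive precedence SE1 > SE2 > SE3 > promoter
binding (VP) > TE: a gene under a rarer, more specific pattern should
not also count toward the broader class. Density correlations are
Pearson on log2(rpm/bp) with Bonferroni adjustment; zero densities are
floored at ε = 0.001 rpm/bp before the log so vectors stay finite — the
floor only affects regions with no signal at all, and sensitivity to ε
is limited to those. GC content is (G+C)/(A+C+G+T) case-insensitive
with N excluded from the denominator; an all-N region is `NA`, not 0.

## Pre-ranked GSEA

Walking a descending ranking, set members increment the running sum by
|score|ᵖ/Σ_hits|score|ᵖ and non-members decrement by 1/(N − N_hits); the
enrichment score is the signed value at the maximal absolute deviation
(first such index on ties). The default weight is p = 1, the published
GSEA default; p = 0 is exposed because it admits analytic checks — the
running sum telescopes to zero, reversing the ranking negates the score,
a top-k contiguous set scores exactly 1 and a bottom-k set exactly −1
(all N−k misses of 1/(N−k) accumulate before the hits). An all-zero
score vector under p = 1 falls back to equal hit weights instead of
0/0. Significance uses gene-tag permutation — random same-size subsets
of the ranking — which is the only null available to pre-ranked GSEA;
the normalised score divides by the mean |permuted score| of matching
sign. The leading edge is the set members at ranks up to the peak for
positive scores; for negative scores the trailing-edge analogue is
returned and flagged, not silently substituted.

## The synthetic landscape

The generator emulates the statistical structure of a two-condition
TF ChIP-seq study at desk scale. Cluster archetypes are parameterised by
peak composition — persistent-only, persistent+secondary,
secondary-only, persistent+primary, primary-only — from which the
per-condition patterns follow (a persistent-only cluster *is* SE4 before
and SE1 after; an independent "SE4 count" would contradict the
definitions). Defaults: 2 chromosomes × 5 Mb; 5/7/3/4/3 clusters of the
five archetypes; 10 peaks of 500 bp per cluster, 1 kb apart; clusters
and 200 isolated background peaks separated by at least the stitch
distance plus 100 kb; planted coverage 30 rpm/bp over cluster peaks
versus 1 over background with a flat 0.2 input track and Gaussian noise
(sd 0.05); 45 SNPs planted inside after-condition SE clusters at rate
0.9; 120 genes (each cluster's target gene 20 kb downstream, the rest in
peak-free zones) with negative-binomial counts (dispersion 0.1, 3+3
replicates), a planted 4-fold change on SE2/SE3 target genes plus random
genes up to 20% of the panel, and baseline expression spanning four
orders of magnitude with enhancer-target genes drawn from the upper
range, as SE-associated genes are characteristically well expressed.
Secondary-only cluster sequence is GC-rich (0.7 versus 0.5 background),
giving the GC-content contrast a planted signal.

The geometry invariants are what make recovery provable rather than
probable: intra-cluster gaps below the stitch distance and inter-cluster
gaps above it mean stitching reconstructs exactly the planted clusters,
and planted peaks either coincide across conditions or are disjoint, so
dynamics labels are exactly recoverable. Consequently the 100% recovery
the tests demonstrate validates the *logic* of the pipeline, not its
robustness to real data: real peak sets have ragged boundaries, partial
overlaps, copy-number artefacts, density distributions without a clean
two-regime gap, and LD structure among SNPs. None of that is emulated,
and no conclusion about hg19-scale performance should be drawn from the
synthetic results. Coverage is written as already-extended piecewise
bedGraph, sidestepping read-level simulation entirely, because the
pipeline consumes densities, not reads.

## Determinism and problem sizes

Every stochastic stage takes a seed; `run_all()` derives per-stage seeds
from the configuration seed with fixed offsets (simulation +0,
enrichment +101, GSEA +202), records them in the report, and reruns are
byte-identical. The test-suite problem sizes are chosen to exercise the
mathematics at the smallest scale where the checks are exact or
well-powered: oracle equivalence on ~100-peak instances, null
calibration of the enrichment z over 200 replicate datasets at 200
permutations each, exhaustive enumeration on a 100 bp toy chromosome
against 10,000 permutations, and GSEA p-value uniformity over 200
replicates at 100 permutations, with 1,000 permutations (the
procedure's standard) used in the end-to-end runs.

## Known limitations

The two-group Welch test is intentionally naive — at three replicates it
has limited power at low expression and its false-positive control is
approximate for skewed counts; a moderated fit supplied through
`de_flags()` is preferable whenever available. The tangent cutoff
depends mildly on the smoothing window on curves with long plateaus.
LD expansion of tag SNPs, loop-based gene assignment, motif analysis and
GO annotation are out of scope; SNP lists and gene annotations are
consumed as given.
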
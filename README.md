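# SEdynamics

Signal-inducible super-enhancer calling, binding-dynamics classification
and enrichment analysis in R.

## The problem

Super-enhancers (SEs) — stitched clusters of enhancer elements with
unusually high signal density — are classically defined from histone
marks, master transcription factors or open chromatin. A *signal-inducible*
SE is instead defined by the binding of a signalling pathway's terminal
transcription factor, for example the vitamin D receptor (VDR) after
1,25(OH)₂D₃ stimulation of monocytes. Because the TF cistrome changes with
stimulation, these SEs have dynamics: each binding site is **primary**
(present only before stimulation), **persistent** (present in both
conditions) or **secondary** (present only after), and each SE is
classified by the site labels it overlaps:

| condition | persistent only | persistent + changing | changing only |
|-----------|-----------------|-----------------------|---------------|
| after stimulation | SE1 | SE2 | SE3 |
| before stimulation | SE4 | SE5 | SE6 |

`SEdynamics` implements the full analysis as a tested R package for
researchers in regulatory genomics:

- **SE calling** (ROSE procedure): blacklist filtering, exclusion of
  peaks within ±2 kb of any TSS, stitching peaks within 12.5 kb,
  background-subtracted signal density in rpm/bp over the stitched spans,
  and the split of SEs from typical enhancers (TEs) at the point where a
  slope-1 tangent touches the scaled (signal density)/(density rank)
  curve.
- **Dynamics classification**: site labels by ≥1 bp overlap between the
  condition peak sets, SE1–SE6 patterns, and before→after transition
  fates (persist / reclassify / lost).
- **Region enrichment**: permutation test for query features (e.g.,
  disease-risk SNPs) in a region set. The observed overlap count is
  normalised per 10 Mb of region-set size; the null re-places the regions
  uniformly over the genome 1,000 times (widths preserved; blacklist and
  the original set excluded); z = (obs − mean)/sd with |z| > 1.96 as the
  two-sided 5% line, plus a one-sided empirical p.
- **Gene linking**: closest SE within 50 kb (edge-to-edge, ties kept) and
  SNP risk-region proximity (±500 kb).
- **Expression statistics**: CPM filter (>0.5 in ≥2 samples), a
  transparent two-group DE test on log2(CPM + 0.5) with the p < 0.05 and
  |log2FC| ≥ 1 significance rule, Kruskal–Wallis with Dunn post-hoc
  z-tests (tie-corrected, Bonferroni), Pearson density correlations and
  GC content.
- **Pre-ranked GSEA**: weighted running-sum enrichment score
  (hits add |score|ᵖ/Σ|score|ᵖ, misses subtract 1/(N−N_hits)), gene-tag
  permutation significance and leading-edge extraction.
- **Synthetic data generator**: a complete two-condition landscape with
  planted cluster archetypes, SNP enrichment, GC-rich segments and
  expression effects, written as standard files (FASTA, narrowPeak,
  bedGraph, BED, TSV) with a machine-readable truth table — so every
  stage is testable end-to-end without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic landscape (2 × 5 Mb genome; 22 planted SE clusters of five
archetypes; 200 isolated background peaks; 45 SNPs planted into SEs at
rate 0.9; 120 genes, 3+3 RNA-seq replicates):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_superenhancers.R
Rscript analysis/03_classify_dynamics.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_expression_gsea.R
```

Stage 2 prints the SE calls:

```
[before] 305 peaks -> 169 stitched regions -> 19 SE / 150 TE (cutoff 0.951 rpm/bp)
[after]  320 peaks -> 169 stitched regions -> 19 SE / 150 TE (cutoff 0.930 rpm/bp)
```

All 19 after-stimulation SEs are the planted clusters: the 150 TEs are
the isolated low-density background peaks. Stage 3 classifies them:

```
SE pattern census:       before after     Transitions: 9 persist, 7 reclassified, 3 lost
  SE1                         0     9       SE4 regions persisting as SE1: 5
  SE2                         0     7       SE4 regions initiating secondary
  SE3                         0     3         binding (-> SE2): 7
  SE4/SE5/SE6                12/4/3  0
```

exactly matching the planted truth (persistent-only and
persistent+primary clusters both become SE1 after stimulation). Stage 4
shows 36 of 45 SNPs inside SEs and strong enrichment in every SE class
but not in TEs (z = 108.7 for all SEs, 12.5 for SE3, −0.56 for TEs, all
at 1,000 permutations), and stage 5 retains 115 of 120 genes after the
CPM filter, calls 22 significantly regulated, and finds the SE-linked
gene set enriched at the top of the fold-change ranking (ES = 0.59,
NES = 1.93, p = 0.01).

The same pipeline runs as one call from R:

```r
library(SEdynamics)
report <- run_all(sim_config(seed = 1), out_dir = "results/run", n_perm = 1000)
```

which writes `report.json` plus per-stage TSVs, byte-identical across
reruns with the same seed.

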
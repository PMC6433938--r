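#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-condition TF binding landscape.
#
# Produces the full input bundle (genome FASTA, blacklist, vehicle and
# stimulated narrowPeak sets, coverage bedGraphs with input control, gene
# annotation, risk-SNP list, RNA-seq counts) plus truth.json under
# results/inputs/. All later stages read only these files.

suppressMessages(library(SEdynamics))

cfg <- sim_config(seed = 1)
bundle <- simulate_bundle(cfg, "results/inputs")

cl <- bundle$truth$clusters
cat("Simulated genome:", cfg$n_chroms, "chromosomes x",
    cfg$chrom_length / 1e6, "Mb\n")
cat("Planted clusters by archetype:\n")
print(table(cl$archetype))
cat("Expected after-stimulation patterns:\n")
print(table(cl$pattern_after))
cat("Background peaks:", cfg$n_background_peaks,
    "| SNPs:", cfg$n_snps, sprintf("(planting rate %.2f)", cfg$snp_enrichment_rate),
    "| genes:", cfg$n_genes, "\n")
cat("Bundle written to results/inputs/\n")
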
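#!/usr/bin/env Rscript
# Stage 2: ROSE-style super-enhancer calling, per condition.
#
# Blacklist filtering -> TSS exclusion (2 kb) -> stitching (12.5 kb) ->
# background-subtracted rpm/bp density over stitched spans -> slope-1
# tangent cutoff on the ranked density curve. Writes SE/TE BED files and
# the ranked curve per condition under results/.

suppressMessages(library(SEdynamics))

inp <- function(x) file.path("results/inputs", x)
genome <- se_genome(read_chrom_sizes(inp("genome.chrom.sizes")),
                    read_bed(inp("blacklist.bed"), "bed3"))
genes <- read_genes(inp("genes.tsv"), "tsv")
background <- read_bedgraph(inp("background.bedGraph"))

for (cond in c("before", "after")) {
  peaks <- read_bed(inp(sprintf("peaks_%s.narrowPeak", cond)), "narrowPeak")
  signal <- read_bedgraph(inp(sprintf("signal_%s.bedGraph", cond)))
  part <- call_superenhancers(peaks, signal, background, genes, genome)
  cat(sprintf("[%s] %d peaks -> %d stitched regions -> %d SE / %d TE (cutoff %.3f rpm/bp)\n",
              cond, length(peaks), length(part$stitched), length(part$se),
              length(part$te), part$cutoff))
  write_bed(part$se, sprintf("results/%s.SE.bed", cond))
  write_bed(part$te, sprintf("results/%s.TE.bed", cond))
  write.table(part$curve, sprintf("results/%s.curve.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("SE/TE calls and ranked curves written under results/\n")
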
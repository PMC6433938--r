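#!/usr/bin/env Rscript
# Stage 3: binding dynamics and SE1-SE6 pattern classification.
#
# Labels every binding site primary / persistent / secondary by comparing
# the vehicle and stimulated peak sets, classifies each called SE by the
# labels it overlaps (SE1-SE3 after stimulation, SE4-SE6 before), and
# tracks each before-SE's fate across stimulation.

suppressMessages(library(SEdynamics))

inp <- function(x) file.path("results/inputs", x)
blacklist <- read_bed(inp("blacklist.bed"), "bed3")
pk_before <- remove_blacklisted(read_bed(inp("peaks_before.narrowPeak"), "narrowPeak"),
                                blacklist)
pk_after <- remove_blacklisted(read_bed(inp("peaks_after.narrowPeak"), "narrowPeak"),
                               blacklist)
se_before <- read_bed("results/before.SE.bed", "bed3")
se_after <- read_bed("results/after.SE.bed", "bed3")

labels <- label_sites(pk_before, pk_after)
cat("Site labels (vehicle):\n"); print(table(labels$before$label))
cat("Site labels (stimulated):\n"); print(table(labels$after$label))

class_before <- classify_se(se_before, labels$before, "before")
class_after <- classify_se(se_after, labels$after, "after")
cen <- data.frame(pattern = se_pattern_levels(),
                  before = as.integer(pattern_census(class_before)),
                  after = as.integer(pattern_census(class_after)))
cat("SE pattern census:\n"); print(cen)

tr <- transitions(class_before, class_after)
cat(sprintf("Transitions: %d persist, %d reclassified, %d lost\n",
            sum(tr$fate == "persists_as"), sum(tr$fate == "reclassified_as"),
            sum(tr$fate == "lost")))
cat(sprintf("  SE4 regions persisting as SE1: %d; initiating secondary binding (-> SE2): %d\n",
            sum(tr$before_pattern == "SE4" & !is.na(tr$after_pattern) &
                  tr$after_pattern == "SE1"),
            sum(tr$before_pattern == "SE4" & !is.na(tr$after_pattern) &
                  tr$after_pattern == "SE2")))

pat_df <- function(gr) data.frame(
  chrom = as.character(GenomeInfoDb::seqnames(gr)),
  start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
  condition = gr$condition, pattern = as.character(gr$pattern),
  n_persistent = gr$n_persistent, n_primary = gr$n_primary,
  n_secondary = gr$n_secondary)
write.table(rbind(pat_df(class_before), pat_df(class_after)),
            "results/patterns.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tr, "results/transitions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cen, "results/census.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("patterns.tsv, transitions.tsv and census.tsv written under results/\n")
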
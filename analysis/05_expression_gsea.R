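#!/usr/bin/env Rscript
# Stage 5: expression-side statistics and gene-set enrichment.
#
# CPM filtering (>0.5 in >=2 samples), a transparent two-group DE test on
# log2(CPM + 0.5) with the p < 0.05 & |log2FC| >= 1 significance rule,
# Kruskal-Wallis + Dunn (Bonferroni) comparisons of regulatory effect and
# expression level across gene regulatory-pattern groups, gene-SE links
# within 50 kb, and pre-ranked GSEA of the SE-linked gene set in the
# fold-change ranking.

suppressMessages(library(SEdynamics))

inp <- function(x) file.path("results/inputs", x)
genes <- read_genes(inp("genes.tsv"), "tsv")
counts_df <- read.table(inp("counts.tsv"), header = TRUE, sep = "\t",
                        check.names = FALSE)
counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df$gene

filt <- cpm_filter(counts)
grp <- factor(ifelse(grepl("^stimulated", colnames(counts)),
                     "stimulated", "vehicle"),
              levels = c("vehicle", "stimulated"))
de <- simple_de(filt$cpm, grp, stimulated = "stimulated")
cat(sprintf("%d/%d genes pass the CPM filter; %d significantly regulated, %d highly expressed\n",
            length(filt$genes), nrow(counts), sum(de$significant),
            sum(de$highly_expressed)))

patterns <- read.table("results/patterns.tsv", header = TRUE, sep = "\t")
aft <- patterns[patterns$condition == "after", ]
ses <- GenomicRanges::GRanges(aft$chrom, IRanges::IRanges(aft$start + 1, aft$end))
ses$pattern <- factor(aft$pattern, levels = se_pattern_levels())
te <- read_bed("results/after.TE.bed", "bed3")
pk_after <- read_bed(inp("peaks_after.narrowPeak"), "narrowPeak")

links <- closest_within(genes, ses, window = 50000)
cat(sprintf("%d genes link to an SE within 50 kb\n", length(unique(links$gene))))
write.table(links, "results/links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

group <- assign_gene_groups(genes, ses, te, pk_after)
m <- match(genes$name, de$gene)
tbl <- data.frame(group = group, abs_log2fc = abs(de$log2fc[m]),
                  ave_expr = de$ave_expr[m])
tbl <- tbl[!is.na(tbl$abs_log2fc), ]
cmp <- kruskal_dunn(split(tbl$abs_log2fc, tbl$group))
cat(sprintf("Regulatory effect (|log2FC|) differs across pattern groups: Kruskal-Wallis p = %.3g\n",
            cmp$kw_p))
print(cmp$pairwise, row.names = FALSE)

ord <- order(de$log2fc, decreasing = TRUE)
gsea <- gsea_test(de$gene[ord], de$log2fc[ord],
                  intersect(unique(links$gene), de$gene),
                  weight = 1, n_perm = 1000, seed = 203)
cat(sprintf("GSEA of the SE-linked gene set: ES = %.3f (NES %.2f), p = %.4g, leading edge %d genes\n",
            gsea$es, gsea$nes, gsea$p_perm, length(gsea$leading_edge)))

write.table(de, "results/de.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(gsea = list(es = gsea$es, nes = gsea$nes, p_perm = gsea$p_perm,
                   leading_edge = gsea$leading_edge),
       kruskal_wallis_p = cmp$kw_p),
  "results/expression_gsea.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("de.tsv, links.tsv and expression_gsea.json written under results/\n")
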
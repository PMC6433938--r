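#' Assign genes to mutually exclusive regulatory-pattern groups
#'
#' Each gene is assigned the pattern of its linked super-enhancer(s) within
#' `window` bp, with precedence SE1 > SE2 > SE3 > VP > TE > none: VP marks
#' genes with a TF peak in their promoter window, TE genes linked only to
#' typical enhancers. The precedence makes the grouping mutually exclusive
#' for group-comparison statistics.
#'
#' @param genes `GRanges` of gene bodies with `name`.
#' @param ses Classified SE `GRanges` (with `pattern`), e.g. after
#'   stimulation.
#' @param tes `GRanges` of typical enhancers.
#' @param peaks `GRanges` of TF peaks (for promoter binding).
#' @param window Link window in bp (default 50000).
#' @param tss_flank Promoter flank in bp (default 2000).
#' @return Character vector per gene: one of SE1, SE2, SE3, VP, TE, none.
#' @export
assign_gene_groups <- function(genes, ses, tes, peaks, window = 50000,
                               tss_flank = 2000) {
  group <- rep("none", length(genes))
  if (length(tes) > 0) {
    lt <- closest_within(genes, tes, window = window)
    group[unique(lt$gene_index)] <- "TE"
  }
  if (length(peaks) > 0 && length(genes) > 0) {
    prom <- suppressWarnings(
      GenomicRanges::promoters(genes, upstream = tss_flank,
                               downstream = tss_flank))
    prom <- IRanges::restrict(prom, start = 1L)
    group[IRanges::overlapsAny(prom, peaks, ignore.strand = TRUE)] <- "VP"
  }
  if (length(ses) > 0) {
    ls <- closest_within(genes, ses, window = window)
    for (pat in c("SE3", "SE2", "SE1")) {  # ascending precedence
      idx <- unique(ls$gene_index[ls$pattern == pat])
      group[idx] <- pat
    }
  }
  group
}

#' Run the full analysis end-to-end on a synthetic bundle
#'
#' Orchestrates simulate, SE calling per condition, dynamics labelling and
#' SE1-SE6 classification, before/after transitions, gene linking, SNP
#' enrichment per pattern, expression statistics (CPM filter, two-group DE,
#' Kruskal-Wallis/Dunn group comparisons of expression level and regulatory
#' effect), GSEA of the SE-linked gene set in the fold-change ranking, GC
#' content contrasts, and truth-recovery metrics. All generated inputs are
#' round-tripped through the package's own file readers. Every stochastic
#' stage is seeded from `config$seed` with fixed per-stage offsets
#' (simulation `+0`, enrichment `+101`, GSEA `+202`), so a rerun with the
#' same configuration reproduces the report byte-for-byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; inputs go to `out_dir/inputs`, tables
#'   and `report.json` to `out_dir`.
#' @param n_perm Permutations for enrichment and GSEA (default 1000).
#' @param gene_window Gene-SE link window in bp (default 50000).
#' @param snp_window SNP risk-region flank in bp (default 500000).
#' @param gsea_weight GSEA weight exponent (default 1).
#' @return Invisibly, the report list (also written as
#'   `out_dir/report.json`).
#' @export
run_all <- function(config = sim_config(), out_dir, n_perm = 1000,
                    gene_window = 50000, snp_window = 500000,
                    gsea_weight = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_bundle(config, file.path(out_dir, "inputs"))
  f <- bundle$files
  for (nm in names(f))
    if (!file.exists(f[[nm]]))
      stop("missing input file: ", f[[nm]], call. = FALSE)

  ## ---- read everything back through the package readers ------------
  chrom_sizes <- read_chrom_sizes(f$chrom_sizes)
  blacklist <- read_bed(f$blacklist, "bed3")
  genome <- se_genome(chrom_sizes, blacklist)
  peaks_before <- read_bed(f$peaks_before, "narrowPeak")
  peaks_after <- read_bed(f$peaks_after, "narrowPeak")
  signal_before <- read_bedgraph(f$signal_before)
  signal_after <- read_bedgraph(f$signal_after)
  background <- read_bedgraph(f$background)
  genes <- read_genes(f$genes, "tsv")
  snps <- read_bed(f$snps, "bed3")
  counts_df <- utils::read.table(f$counts, sep = "\t", header = TRUE,
                                 check.names = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene
  total_reads <- bundle$truth$total_mapped_reads

  ## ---- super-enhancer calling per condition ------------------------
  part_before <- call_superenhancers(
    peaks_before, signal_before, background, genes, genome,
    total_reads_signal = total_reads, total_reads_background = total_reads,
    tss_flank = config$tss_flank, stitch_distance = config$stitch_distance)
  part_after <- call_superenhancers(
    peaks_after, signal_after, background, genes, genome,
    total_reads_signal = total_reads, total_reads_background = total_reads,
    tss_flank = config$tss_flank, stitch_distance = config$stitch_distance)

  ## ---- binding dynamics and SE patterns ----------------------------
  labels <- label_sites(remove_blacklisted(peaks_before, blacklist),
                        remove_blacklisted(peaks_after, blacklist))
  class_before <- classify_se(part_before$se, labels$before, "before")
  class_after <- classify_se(part_after$se, labels$after, "after")
  census_before <- pattern_census(class_before)
  census_after <- pattern_census(class_after)
  trans <- transitions(class_before, class_after)

  ## ---- gene linking and SNP proximity ------------------------------
  links <- closest_within(genes, class_after, window = gene_window)
  snps_in_se <- count_overlapping_features(snps, class_after)
  se_near_snp <- snp_proximity(class_after, snps, window = snp_window)

  ## ---- SNP enrichment per pattern ----------------------------------
  sets <- list(SE = GenomicRanges::granges(class_after),
               SE1 = GenomicRanges::granges(class_after[class_after$pattern == "SE1"]),
               SE2 = GenomicRanges::granges(class_after[class_after$pattern == "SE2"]),
               SE3 = GenomicRanges::granges(class_after[class_after$pattern == "SE3"]),
               TE = GenomicRanges::granges(part_after$te))
  enr <- enrichment_by_pattern(snps, sets, genome, n_perm = n_perm,
                               seed = config$seed + 101)

  ## ---- expression statistics ---------------------------------------
  filt <- cpm_filter(counts)
  sample_group <- ifelse(grepl("^stimulated", colnames(counts)),
                         "stimulated", "vehicle")
  de <- simple_de(filt$cpm, factor(sample_group,
                                   levels = c("vehicle", "stimulated")),
                  stimulated = "stimulated")
  gene_group <- assign_gene_groups(genes, class_after, part_after$te,
                                   labels$after, window = gene_window,
                                   tss_flank = config$tss_flank)
  gidx <- match(genes$name, de$gene)
  grp_tbl <- data.frame(gene = genes$name, group = gene_group,
                        abs_log2fc = abs(de$log2fc[gidx]),
                        ave_expr = de$ave_expr[gidx],
                        stringsAsFactors = FALSE)
  grp_tbl <- grp_tbl[!is.na(grp_tbl$abs_log2fc), ]
  mk_groups <- function(col) {
    gs <- split(grp_tbl[[col]], grp_tbl$group)
    gs[vapply(gs, length, integer(1)) > 0]
  }
  cmp_effect <- cmp_expr <- NULL
  if (length(unique(grp_tbl$group)) >= 2) {
    cmp_effect <- kruskal_dunn(mk_groups("abs_log2fc"))
    cmp_expr <- kruskal_dunn(mk_groups("ave_expr"))
  }

  ## ---- GSEA of the SE-linked gene set ------------------------------
  gsea <- NULL
  ord <- order(de$log2fc, decreasing = TRUE)
  ranked_genes <- de$gene[ord]
  ranked_scores <- de$log2fc[ord]
  se_set <- intersect(unique(links$gene), ranked_genes)
  if (length(se_set) > 0 && length(se_set) < length(ranked_genes))
    gsea <- gsea_test(ranked_genes, ranked_scores, se_set,
                      weight = gsea_weight, n_perm = n_perm,
                      seed = config$seed + 202)

  ## ---- GC content contrast -----------------------------------------
  sequences <- Biostrings::readDNAStringSet(f$genome_fasta)
  names(sequences) <- sub(" .*", "", names(sequences))
  gc_se3 <- gc_content(class_after[class_after$pattern == "SE3"], sequences)
  gc_te <- gc_content(part_after$te, sequences)

  ## ---- recovery against planted truth ------------------------------
  recovery <- verify_recovery(bundle$truth, class_before, class_after,
                              labels = labels, enrichment = enr, de = de)

  ## ---- write tables and report -------------------------------------
  wt <- function(df, name)
    write_plain(df, file.path(out_dir, name), col.names = TRUE)
  pat_df <- function(gr) data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    condition = gr$condition, pattern = as.character(gr$pattern),
    n_persistent = gr$n_persistent, n_primary = gr$n_primary,
    n_secondary = gr$n_secondary)
  wt(rbind(pat_df(class_before), pat_df(class_after)), "patterns.tsv")
  wt(trans, "transitions.tsv")
  wt(data.frame(pattern = names(census_after),
                before = as.integer(census_before),
                after = as.integer(census_after)), "census.tsv")
  wt(enr, "enrichment.tsv")
  wt(links, "links.tsv")
  wt(de, "de.tsv")
  if (!is.null(part_after$curve)) wt(part_after$curve, "curve_after.tsv")
  if (!is.null(part_before$curve)) wt(part_before$curve, "curve_before.tsv")

  report <- list(
    schema = 1,
    params = list(seed = config$seed, n_perm = n_perm,
                  tss_flank = config$tss_flank,
                  stitch_distance = config$stitch_distance,
                  gene_window = gene_window, snp_window = snp_window,
                  gsea_weight = gsea_weight, z_crit = 1.96,
                  seed_enrichment = config$seed + 101,
                  seed_gsea = config$seed + 202),
    se_calling = list(
      n_stitched_before = length(part_before$stitched),
      n_se_before = length(part_before$se),
      n_te_before = length(part_before$te),
      cutoff_before = part_before$cutoff,
      n_stitched_after = length(part_after$stitched),
      n_se_after = length(part_after$se),
      n_te_after = length(part_after$te),
      cutoff_after = part_after$cutoff),
    census = list(before = as.list(census_before),
                  after = as.list(census_after)),
    transitions = list(
      n_lost = sum(trans$fate == "lost"),
      n_persists = sum(trans$fate == "persists_as"),
      n_reclassified = sum(trans$fate == "reclassified_as"),
      se4_to_se1 = sum(trans$before_pattern == "SE4" &
                         !is.na(trans$after_pattern) &
                         trans$after_pattern == "SE1"),
      se4_to_se2 = sum(trans$before_pattern == "SE4" &
                         !is.na(trans$after_pattern) &
                         trans$after_pattern == "SE2")),
    gene_links = list(n_links = nrow(links),
                      n_genes_linked = length(unique(links$gene))),
    snps = list(n_snps = length(snps), n_in_se = snps_in_se,
                n_se_near_snp = sum(se_near_snp)),
    enrichment = enr,
    expression = list(
      n_genes_input = nrow(counts), n_genes_retained = sum(filt$keep),
      n_significant = sum(de$significant),
      n_highly_expressed = sum(de$highly_expressed)),
    group_comparison = list(
      effect_kw_p = if (!is.null(cmp_effect)) cmp_effect$kw_p else NA,
      expression_kw_p = if (!is.null(cmp_expr)) cmp_expr$kw_p else NA,
      effect_pairwise = if (!is.null(cmp_effect)) cmp_effect$pairwise else NULL,
      expression_pairwise = if (!is.null(cmp_expr)) cmp_expr$pairwise else NULL),
    gsea = if (!is.null(gsea)) list(es = gsea$es, nes = gsea$nes,
                                    p_perm = gsea$p_perm,
                                    p_one_sided = gsea$p_one_sided,
                                    n_leading_edge = length(gsea$leading_edge),
                                    leading_edge = gsea$leading_edge)
           else NULL,
    gc = list(mean_gc_se3 = mean(gc_se3, na.rm = TRUE),
              mean_gc_te = mean(gc_te, na.rm = TRUE)),
    recovery = recovery)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
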
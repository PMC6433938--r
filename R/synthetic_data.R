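# Synthetic two-condition ChIP-seq landscape with planted super-enhancer
# dynamics, SNP enrichment and expression effects, plus a machine-readable
# truth table. The generator emulates the statistical structure of the real
# study inputs (vehicle vs stimulated TF peak sets, coverage tracks with an
# input control, gene annotation, risk-SNP list, RNA-seq counts) at desk
# scale, so every pipeline stage is testable without downloads.

#' Simulation configuration
#'
#' Cluster archetypes are parameterised by peak composition, from which the
#' per-condition SE1-SE6 patterns follow: persistent-only clusters are SE4
#' before and SE1 after stimulation; persistent+secondary are SE4 before
#' (only their persistent peaks exist yet) and SE2 after; secondary-only
#' appear only after (SE3); persistent+primary are SE5 before and SE1
#' after; primary-only are SE6 before and disappear after.
#'
#' Geometry invariants guarantee exact recovery: peaks within a cluster are
#' separated by less than the stitch distance, clusters (and isolated
#' background peaks) by more, so stitching reconstructs exactly the planted
#' clusters; planted before/after peaks either coincide (persistent) or are
#' disjoint, so dynamics labels are recoverable exactly.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 5 Mb).
#' @param n_persistent_only,n_persistent_secondary,n_secondary_only,n_persistent_primary,n_primary_only
#'   Cluster counts per archetype (defaults 5/7/3/4/3).
#' @param peaks_per_cluster,peak_width,intra_cluster_gap Cluster geometry
#'   (defaults 10 peaks of 500 bp separated by 1 kb).
#' @param inter_cluster_gap Spacing between clusters and from background
#'   peaks (default 150 kb; must exceed `stitch_distance` + 100 kb).
#' @param stitch_distance,tss_flank Pipeline geometry the layout respects
#'   (defaults 12500 and 2000 bp).
#' @param n_background_peaks Isolated low-density peaks (default 200).
#' @param density_high,density_low Planted coverage (rpm/bp at a library of
#'   `total_mapped_reads`) over cluster and background peaks (defaults
#'   30 and 1).
#' @param background_coverage Input-control coverage over the whole genome
#'   (default 0.2).
#' @param noise_sd Gaussian sd added to per-peak coverage (default 0.05).
#' @param total_mapped_reads Nominal library size for all tracks (1e6, so
#'   coverage values are directly rpm/bp).
#' @param n_genes,n_snps Annotation sizes (defaults 120 genes, 45 SNPs).
#' @param snp_enrichment_rate Probability that a SNP is planted inside an
#'   (after-condition) SE cluster instead of uniformly (default 0.9).
#' @param de_fraction,de_log2fc Fraction of genes with a planted expression
#'   effect and its magnitude (defaults 0.2 and 2); SE2/SE3 target genes
#'   are planted first.
#' @param nb_dispersion Negative-binomial dispersion of counts (0.1).
#' @param n_samples_per_group RNA-seq replicates per condition (3).
#' @param gc_background,gc_se3 GC composition of the genome sequence and of
#'   secondary-only (SE3) cluster spans (defaults 0.5 and 0.7).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 5e6,
                       n_persistent_only = 5, n_persistent_secondary = 7,
                       n_secondary_only = 3, n_persistent_primary = 4,
                       n_primary_only = 3,
                       peaks_per_cluster = 10, peak_width = 500,
                       intra_cluster_gap = 1000, inter_cluster_gap = 150000,
                       stitch_distance = 12500, tss_flank = 2000,
                       n_background_peaks = 200,
                       density_high = 30, density_low = 1,
                       background_coverage = 0.2, noise_sd = 0.05,
                       total_mapped_reads = 1e6,
                       n_genes = 120, n_snps = 45, snp_enrichment_rate = 0.9,
                       de_fraction = 0.2, de_log2fc = 2, nb_dispersion = 0.1,
                       n_samples_per_group = 3,
                       gc_background = 0.5, gc_se3 = 0.7) {
  cfg <- as.list(environment())
  if (!(cfg$intra_cluster_gap < cfg$stitch_distance))
    stop("intra_cluster_gap must be < stitch_distance", call. = FALSE)
  if (!(cfg$inter_cluster_gap > cfg$stitch_distance + 100000))
    stop("inter_cluster_gap must exceed stitch_distance + 100 kb", call. = FALSE)
  if (cfg$snp_enrichment_rate < 0 || cfg$snp_enrichment_rate > 1)
    stop("snp_enrichment_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

archetype_patterns <- function(archetype) {
  switch(archetype,
         persistent_only = c(before = "SE4", after = "SE1"),
         persistent_secondary = c(before = "SE4", after = "SE2"),
         secondary_only = c(before = "ABSENT", after = "SE3"),
         persistent_primary = c(before = "SE5", after = "SE1"),
         primary_only = c(before = "SE6", after = "ABSENT"),
         stop("unknown archetype: ", archetype))
}

# deterministic genome layout; errors before writing if infeasible
sim_layout <- function(cfg) {
  span <- cfg$peaks_per_cluster * cfg$peak_width +
    (cfg$peaks_per_cluster - 1) * cfg$intra_cluster_gap
  archetypes <- rep(c("persistent_only", "persistent_secondary",
                      "secondary_only", "persistent_primary", "primary_only"),
                    times = c(cfg$n_persistent_only, cfg$n_persistent_secondary,
                              cfg$n_secondary_only, cfg$n_persistent_primary,
                              cfg$n_primary_only))
  n_cl <- length(archetypes)
  L <- cfg$chrom_length
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  peak_zone_end <- L - 1.2e6
  bg_stride <- cfg$stitch_distance + 1000 + cfg$peak_width
  # cluster stride includes its downstream target gene (20 kb away, 5 kb)
  cl_stride <- span + cfg$inter_cluster_gap

  cursor <- 50001; chrom_i <- 1
  place <- function(width, stride) {
    if (cursor + width - 1 > peak_zone_end) {
      chrom_i <<- chrom_i + 1
      if (chrom_i > cfg$n_chroms)
        stop("geometry infeasible: chrom_length too small for the requested clusters/peaks",
             call. = FALSE)
      cursor <<- 50001
    }
    out <- list(chrom = chrom_names[chrom_i], start = cursor,
                end = cursor + width - 1)
    cursor <<- cursor + stride
    out
  }
  clusters <- lapply(seq_len(n_cl), function(i) place(span, cl_stride))
  bg <- lapply(seq_len(cfg$n_background_peaks),
               function(i) place(cfg$peak_width, bg_stride))
  list(archetypes = archetypes, span = span,
       clusters = do.call(rbind, lapply(clusters, as.data.frame)),
       background = do.call(rbind, lapply(bg, as.data.frame)),
       chrom_names = chrom_names,
       blacklist = data.frame(
         chrom = rep(chrom_names, each = 2),
         start = rep(c(L - 1.18e6 + 1, L - 1.12e6 + 1), cfg$n_chroms),
         end = rep(c(L - 1.18e6 + 2e4, L - 1.12e6 + 2e4), cfg$n_chroms)),
       gene_zone = data.frame(chrom = chrom_names,
                              start = L - 1e6 + 1, end = L - 5e4))
}

#' Generate a complete synthetic input bundle with truth table
#'
#' Writes a genome FASTA and chrom.sizes, blacklist BED, two-condition
#' narrowPeak files, pre-extended piecewise-constant coverage bedGraphs
#' (signal per condition plus a flat input control), a 5-column gene TSV, a
#' SNP BED, an RNA-seq counts TSV, and `truth.json` recording every planted
#' entity. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `files` (named paths), `truth` (list of
#'   data.frames: `clusters`, `peaks`, `snps`, `genes`), `config`.
#' @export
simulate_bundle <- function(config = sim_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- sim_layout(cfg)
  with_seed(cfg$seed, {
    n_cl <- length(lay$archetypes)
    # shuffle archetype order across the genome so patterns are interleaved
    ord <- sample.int(n_cl)
    archetypes <- lay$archetypes[ord]

    ## ---- peaks -------------------------------------------------------
    half <- floor(cfg$peaks_per_cluster / 2)
    peak_rows <- list()
    clusters <- lay$clusters
    clusters$archetype <- archetypes
    clusters$id <- sprintf("cluster_%02d", seq_len(n_cl))
    for (i in seq_len(n_cl)) {
      at <- archetypes[i]
      starts <- clusters$start[i] +
        (seq_len(cfg$peaks_per_cluster) - 1) * (cfg$peak_width + cfg$intra_cluster_gap)
      presence <- switch(at,
        persistent_only = rep("both", cfg$peaks_per_cluster),
        persistent_secondary = rep(c("both", "after_only"),
                                   c(half, cfg$peaks_per_cluster - half)),
        secondary_only = rep("after_only", cfg$peaks_per_cluster),
        persistent_primary = rep(c("both", "before_only"),
                                 c(half, cfg$peaks_per_cluster - half)),
        primary_only = rep("before_only", cfg$peaks_per_cluster))
      peak_rows[[i]] <- data.frame(
        chrom = clusters$chrom[i], start = starts,
        end = starts + cfg$peak_width - 1,
        presence = presence, density = cfg$density_high,
        cluster_id = clusters$id[i], stringsAsFactors = FALSE)
    }
    bg_presence <- rep(c("both", "before_only", "both", "after_only"),
                       length.out = cfg$n_background_peaks)
    peak_rows[[n_cl + 1]] <- data.frame(
      chrom = lay$background$chrom, start = lay$background$start,
      end = lay$background$end, presence = bg_presence,
      density = cfg$density_low, cluster_id = NA_character_,
      stringsAsFactors = FALSE)
    peaks <- do.call(rbind, peak_rows)
    peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))
    peaks$label_before <- ifelse(peaks$presence == "both", "PERSISTENT",
                          ifelse(peaks$presence == "before_only", "PRIMARY", NA))
    peaks$label_after <- ifelse(peaks$presence == "both", "PERSISTENT",
                         ifelse(peaks$presence == "after_only", "SECONDARY", NA))

    ## ---- cluster truth patterns -------------------------------------
    pats <- t(vapply(archetypes, archetype_patterns, character(2)))
    clusters$pattern_before <- pats[, "before"]
    clusters$pattern_after <- pats[, "after"]

    ## ---- genes -------------------------------------------------------
    gene_width <- 5000
    tg_start <- clusters$end + 20000 + 1
    target <- data.frame(chrom = clusters$chrom, start = tg_start,
                         end = tg_start + gene_width - 1, strand = "+",
                         stringsAsFactors = FALSE)
    n_filler <- max(0, cfg$n_genes - n_cl)
    filler <- list()
    stride <- 8000
    zone <- lay$gene_zone
    fi <- 0; zi <- 1; pos <- zone$start[1]
    while (fi < n_filler) {
      if (pos + gene_width - 1 > zone$end[zi]) {
        zi <- zi + 1
        if (zi > nrow(zone))
          stop("geometry infeasible: not enough room for filler genes", call. = FALSE)
        pos <- zone$start[zi]
      }
      fi <- fi + 1
      filler[[fi]] <- data.frame(chrom = zone$chrom[zi], start = pos,
                                 end = pos + gene_width - 1,
                                 strand = if (fi %% 2 == 0) "-" else "+",
                                 stringsAsFactors = FALSE)
      pos <- pos + stride
    }
    genes <- rbind(target, do.call(rbind, filler))
    genes$name <- sprintf("gene_%03d", seq_len(nrow(genes)))
    clusters$target_gene <- genes$name[seq_len(n_cl)]

    ## ---- expression truth -------------------------------------------
    n_de <- floor(cfg$de_fraction * nrow(genes))
    de_idx <- which(clusters$archetype %in%
                      c("persistent_secondary", "secondary_only"))
    extra_pool <- setdiff(seq_len(nrow(genes)), de_idx)
    n_extra <- max(0, n_de - length(de_idx))
    extra <- if (n_extra > 0) sample(extra_pool, n_extra) else integer(0)
    genes$true_log2fc <- 0
    genes$true_log2fc[de_idx] <- cfg$de_log2fc
    genes$true_log2fc[extra] <- cfg$de_log2fc *
      rep(c(1, -1), length.out = length(extra))
    genes$is_de <- genes$true_log2fc != 0

    ## ---- SNPs --------------------------------------------------------
    # planting target: clusters that are SEs after stimulation
    se_after <- clusters[clusters$pattern_after != "ABSENT", ]
    chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   lay$chrom_names)
    bl <- lay$blacklist
    inside_draw <- runif(cfg$n_snps) < cfg$snp_enrichment_rate
    snp_chrom <- character(cfg$n_snps); snp_pos <- numeric(cfg$n_snps)
    for (i in seq_len(cfg$n_snps)) {
      if (inside_draw[i] && nrow(se_after) > 0) {
        j <- sample.int(nrow(se_after), 1)
        snp_chrom[i] <- se_after$chrom[j]
        snp_pos[i] <- floor(runif(1, se_after$start[j], se_after$end[j] + 1))
      } else {
        repeat {
          ch <- sample(names(chrom_sizes), 1,
                       prob = chrom_sizes / sum(chrom_sizes))
          p <- floor(runif(1, 1, chrom_sizes[[ch]] + 1))
          in_bl <- any(bl$chrom == ch & bl$start <= p & bl$end >= p)
          if (!in_bl) { snp_chrom[i] <- ch; snp_pos[i] <- p; break }
        }
      }
    }
    inside <- vapply(seq_len(cfg$n_snps), function(i) {
      any(se_after$chrom == snp_chrom[i] & se_after$start <= snp_pos[i] &
            se_after$end >= snp_pos[i])
    }, logical(1))
    snps <- data.frame(name = sprintf("snp_%03d", seq_len(cfg$n_snps)),
                       chrom = snp_chrom, pos = snp_pos,
                       planted_inside = inside_draw, inside = inside,
                       stringsAsFactors = FALSE)

    ## ---- counts ------------------------------------------------------
    ns <- cfg$n_samples_per_group
    # baseline means span ~4 orders of magnitude so that, after CPM
    # normalisation over this small gene panel, average log2 expression
    # straddles the conventional high-expression line at 5; enhancer-target
    # genes draw from the upper range, as SE-associated genes are
    # characteristically well expressed
    base_mean <- 2^runif(nrow(genes), -2, 12)
    base_mean[seq_len(n_cl)] <- 2^runif(n_cl, 4, 12)
    mu_veh <- base_mean
    mu_stim <- base_mean * 2^genes$true_log2fc
    size <- 1 / cfg$nb_dispersion
    counts <- cbind(
      matrix(stats::rnbinom(nrow(genes) * ns, mu = rep(mu_veh, ns), size = size),
             ncol = ns),
      matrix(stats::rnbinom(nrow(genes) * ns, mu = rep(mu_stim, ns), size = size),
             ncol = ns))
    dimnames(counts) <- list(genes$name,
                             c(paste0("vehicle_", seq_len(ns)),
                               paste0("stimulated_", seq_len(ns))))

    ## ---- coverage tracks --------------------------------------------
    cov_track <- function(cond) {
      keep <- if (cond == "before") peaks$presence %in% c("both", "before_only")
              else peaks$presence %in% c("both", "after_only")
      p <- peaks[keep, ]
      val <- pmax(0.01, p$density + stats::rnorm(nrow(p), 0, cfg$noise_sd))
      data.frame(chrom = p$chrom, start = p$start, end = p$end, value = val)
    }
    cov_before <- cov_track("before")
    cov_after <- cov_track("after")
    cov_input <- data.frame(chrom = lay$chrom_names, start = 1,
                            end = cfg$chrom_length,
                            value = cfg$background_coverage)

    ## ---- genome sequence --------------------------------------------
    draw_seq <- function(n, gc) {
      sample(c("A", "C", "G", "T"), n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }
    seqs <- lapply(lay$chrom_names, function(ch) {
      s <- draw_seq(cfg$chrom_length, cfg$gc_background)
      rich <- clusters[clusters$archetype == "secondary_only" &
                         clusters$chrom == ch, ]
      if (nrow(rich) > 0)
        for (k in seq_len(nrow(rich)))
          s[rich$start[k]:rich$end[k]] <-
            draw_seq(rich$end[k] - rich$start[k] + 1, cfg$gc_se3)
      paste(s, collapse = "")
    })
    genome_seq <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome_seq) <- lay$chrom_names

    ## ---- write the bundle -------------------------------------------
    wt <- function(df, path) write_plain(df, path)
    files <- list(
      genome_fasta = file.path(dir, "genome.fa"),
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      blacklist = file.path(dir, "blacklist.bed"),
      peaks_before = file.path(dir, "peaks_before.narrowPeak"),
      peaks_after = file.path(dir, "peaks_after.narrowPeak"),
      signal_before = file.path(dir, "signal_before.bedGraph"),
      signal_after = file.path(dir, "signal_after.bedGraph"),
      background = file.path(dir, "background.bedGraph"),
      genes = file.path(dir, "genes.tsv"),
      snps = file.path(dir, "snps.bed"),
      counts = file.path(dir, "counts.tsv"),
      truth = file.path(dir, "truth.json"))

    Biostrings::writeXStringSet(genome_seq, files$genome_fasta)
    wt(data.frame(lay$chrom_names, cfg$chrom_length), files$chrom_sizes)
    wt(data.frame(bl$chrom, bl$start - 1, bl$end), files$blacklist)
    np <- function(p, cond) {
      keep <- if (cond == "before") p$presence %in% c("both", "before_only")
              else p$presence %in% c("both", "after_only")
      p <- p[keep, ]
      data.frame(p$chrom, p$start - 1, p$end, p$name,
                 pmin(1000L, as.integer(round(p$density * 10))), ".",
                 p$density, -1, -1, floor(cfg$peak_width / 2))
    }
    wt(np(peaks, "before"), files$peaks_before)
    wt(np(peaks, "after"), files$peaks_after)
    bg_out <- function(cv) data.frame(cv$chrom, cv$start - 1, cv$end,
                                      round(cv$value, 4))
    wt(bg_out(cov_before), files$signal_before)
    wt(bg_out(cov_after), files$signal_after)
    wt(bg_out(cov_input), files$background)
    wt(data.frame(genes$name, genes$chrom, genes$start - 1, genes$end,
                  genes$strand), files$genes)
    wt(data.frame(snps$chrom, snps$pos - 1, snps$pos, snps$name), files$snps)
    write_plain(data.frame(gene = rownames(counts), counts, check.names = FALSE),
                files$counts, col.names = TRUE)

    truth <- list(clusters = clusters[, c("id", "chrom", "start", "end",
                                          "archetype", "pattern_before",
                                          "pattern_after", "target_gene")],
                  peaks = peaks[, c("name", "chrom", "start", "end", "presence",
                                    "label_before", "label_after", "cluster_id",
                                    "density")],
                  snps = snps,
                  genes = genes[, c("name", "chrom", "start", "end", "strand",
                                    "true_log2fc", "is_de")],
                  total_mapped_reads = cfg$total_mapped_reads,
                  config = unclass(cfg))
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(files = files, truth = truth, config = cfg))
  })
}

#' Compare pipeline outputs against the planted truth
#'
#' Reports per-stage recovery rates: the fraction of planted clusters
#' recovered as called SEs per condition, pattern-label accuracy,
#' binding-dynamics label accuracy, and (when supplied) SNP-enrichment
#' z-scores and differential-expression recall at the significance
#' thresholds.
#'
#' @param truth Truth list from [simulate_bundle()].
#' @param class_before,class_after Classified SE `GRanges` from
#'   [classify_se()] for each condition.
#' @param labels Labelled peak sets from [label_sites()] (optional).
#' @param enrichment Data.frame from [enrichment_by_pattern()] (optional).
#' @param de DE table from [simple_de()] (optional).
#' @return A list of recovery metrics.
#' @export
verify_recovery <- function(truth, class_before, class_after, labels = NULL,
                            enrichment = NULL, de = NULL) {
  cl <- as.data.frame(truth$clusters)
  cl_gr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end))
  check_cond <- function(called, expected_col) {
    expected <- cl[[expected_col]] != "ABSENT"
    if (!any(expected)) return(list(se_recovered = NA_real_, pattern_accuracy = NA_real_))
    idx <- which(expected)
    hit <- GenomicRanges::findOverlaps(cl_gr[idx], called, ignore.strand = TRUE)
    found <- unique(S4Vectors::queryHits(hit))
    se_recovered <- length(found) / length(idx)
    ok <- 0L
    for (k in found) {
      called_pat <- as.character(
        called$pattern[S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == k]])
      if (all(called_pat == cl[[expected_col]][idx[k]])) ok <- ok + 1L
    }
    list(se_recovered = se_recovered,
         pattern_accuracy = if (length(found) > 0) ok / length(found) else NA_real_)
  }
  before <- check_cond(class_before, "pattern_before")
  after <- check_cond(class_after, "pattern_after")

  dyn_acc <- NULL
  if (!is.null(labels)) {
    tp <- as.data.frame(truth$peaks)
    key <- function(gr) sprintf("%s:%d-%d",
                                as.character(GenomeInfoDb::seqnames(gr)),
                                BiocGenerics::start(gr), BiocGenerics::end(gr))
    acc_one <- function(called, truth_col) {
      t_sub <- tp[!is.na(tp[[truth_col]]), ]
      tkey <- sprintf("%s:%d-%d", t_sub$chrom, t_sub$start, t_sub$end)
      m <- match(key(called), tkey)
      mean(as.character(called$label) == t_sub[[truth_col]][m], na.rm = TRUE)
    }
    dyn_acc <- mean(c(acc_one(labels$before, "label_before"),
                      acc_one(labels$after, "label_after")))
  }

  out <- list(
    se_recovered_before = before$se_recovered,
    se_recovered_after = after$se_recovered,
    pattern_accuracy_before = before$pattern_accuracy,
    pattern_accuracy_after = after$pattern_accuracy,
    dynamics_label_accuracy = dyn_acc)
  if (!is.null(enrichment)) out$enrichment_z <-
      stats::setNames(enrichment$z, enrichment$label)
  if (!is.null(de)) {
    tg <- as.data.frame(truth$genes)
    m <- match(tg$name, de$gene)
    truly_de <- tg$is_de & !is.na(m)
    out$de_recall <- if (any(truly_de))
      mean(de$significant[m[truly_de]]) else NA_real_
    truly_null <- !tg$is_de & !is.na(m)
    out$de_false_positive_rate <- if (any(truly_null))
      mean(de$significant[m[truly_null]]) else NA_real_
  }
  out
}
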
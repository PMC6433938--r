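# Permutation-based enrichment of point/interval features (e.g., risk SNPs)
# in a region set, with per-10-Mb size normalisation, width-preserving
# randomisation excluding the blacklist and the original regions, z-score
# and empirical p.

#' Count features overlapping a region set
#'
#' Number of features sharing at least one base with the union of the
#' regions; a feature spanning two regions is counted once.
#'
#' @param features `GRanges` of query features (SNPs are 1-bp intervals).
#' @param regions `GRanges` region set.
#' @return Integer count.
#' @export
count_overlapping_features <- function(features, regions) {
  sum(IRanges::overlapsAny(features, regions, ignore.strand = TRUE))
}

# Valid placement gaps: maximal runs of each chromosome not covered by
# `excluded`, as a data.frame(chrom, start, end) in 1-based closed coords.
placement_gaps <- function(genome, excluded) {
  out <- lapply(names(genome$chrom_sizes), function(ch) {
    L <- genome$chrom_sizes[[ch]]
    exc <- excluded[as.character(GenomeInfoDb::seqnames(excluded)) == ch]
    if (length(exc) == 0) return(data.frame(chrom = ch, start = 1, end = L))
    exc <- GenomicRanges::reduce(GenomicRanges::granges(exc), ignore.strand = TRUE)
    s <- BiocGenerics::start(exc); e <- BiocGenerics::end(exc)
    gs <- c(1, e + 1); ge <- c(s - 1, L)
    keep <- gs <= ge
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = gs[keep], end = ge[keep])
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Sample `n_draws` start positions (1-based) for a region of width w over
# the gap table; returns list(chrom_id, start). Chromosome choice is
# implicit: gaps are chosen with probability proportional to their count of
# valid starts, which makes placement uniform over all valid genome
# positions (and chromosome probability proportional to its valid count).
sample_placements <- function(gaps, w, n_draws) {
  valid <- pmax(0, gaps$end - gaps$start + 1 - w + 1)
  total <- sum(valid)
  if (total <= 0) return(NULL)
  cum <- cumsum(valid)
  u <- runif(n_draws) * total
  g <- findInterval(u, cum) + 1L
  offset <- floor(u - c(0, cum)[g])  # 0 .. valid[g]-1
  list(chrom = gaps$chrom[g], start = gaps$start[g] + offset)
}

#' Randomly re-place regions in the genome, preserving widths
#'
#' Each region is placed independently and uniformly over all genome
#' positions where it fits within a chromosome and overlaps neither the
#' blacklist nor the original region set (both excluded from every
#' permutation). Randomised regions may overlap one another; chromosomes
#' are effectively chosen with probability proportional to their count of
#' valid placements.
#'
#' @param regions `GRanges` to randomise.
#' @param genome An [se_genome()].
#' @param seed Optional integer seed for a self-contained draw.
#' @param exclude_original Also exclude the original region set from
#'   placements (default TRUE, as in the enrichment procedure)?
#' @return A `GRanges` of randomised regions, widths preserved.
#' @export
randomize_regions <- function(regions, genome, seed = NULL,
                              exclude_original = TRUE) {
  excluded <- genome$blacklist
  if (exclude_original)
    excluded <- suppressWarnings(
      c(GenomicRanges::granges(excluded), GenomicRanges::granges(regions)))
  gaps <- placement_gaps(genome, excluded)
  widths <- BiocGenerics::width(regions)
  with_seed(seed, {
    chroms <- character(length(regions)); starts <- numeric(length(regions))
    for (i in seq_along(regions)) {
      pl <- sample_placements(gaps, widths[i], 1L)
      if (is.null(pl))
        stop(sprintf("no valid placement for region %d (width %d bp)",
                     i, widths[i]), call. = FALSE)
      chroms[i] <- pl$chrom; starts[i] <- pl$start
    }
    GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = widths))
  })
}

# fast overlap counting on plain vectors: number of features overlapping
# >= 1 region (chromosomes as integer ids)
count_hits_num <- function(f_chr, f_s, f_e, r_chr, r_s, r_e) {
  if (length(f_chr) == 0 || length(r_chr) == 0) return(0L)
  n <- 0L
  for (ch in unique(f_chr)) {
    fi <- f_chr == ch; ri <- r_chr == ch
    if (!any(ri)) next
    fs <- f_s[fi]; fe <- f_e[fi]
    rs <- r_s[ri]; re <- r_e[ri]
    hit <- outer(fs, re, `<=`) & outer(fe, rs, `>=`)
    n <- n + sum(rowSums(hit) > 0)
  }
  n
}

#' Permutation test for feature enrichment in a region set
#'
#' The observed statistic is the number of features overlapping the region
#' set, normalised per 10 Mb of region-set size
#' (`raw / region_set_bp * 1e7`). The null distribution re-places the
#' regions [randomize_regions()]-style `n_perm` times and scores each draw
#' identically (with the original set's size as the normalising constant,
#' since widths are preserved). Reported are the z-score
#' `(observed - null_mean) / null_sd` — with 1.96 as the conventional
#' two-sided 5% significance line — and the one-sided empirical p
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`.
#'
#' @param features `GRanges` of query features.
#' @param regions `GRanges` region set of interest.
#' @param genome An [se_genome()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed; results are deterministic given it.
#' @return An object of class `enrichment_result` with fields
#'   `observed_norm`, `null_mean`, `null_sd`, `z`, `p_empirical`, `n_perm`,
#'   `region_set_bp`, `observed_raw`, `degenerate_null`, `seed`.
#' @export
permutation_test <- function(features, regions, genome, n_perm = 1000,
                             seed = NULL) {
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  region_set_bp <- sum(BiocGenerics::width(
    GenomicRanges::reduce(GenomicRanges::granges(regions), ignore.strand = TRUE)))
  obs_raw <- count_overlapping_features(features, regions)
  obs_norm <- obs_raw / region_set_bp * 1e7

  excluded <- suppressWarnings(c(GenomicRanges::granges(genome$blacklist),
                                 GenomicRanges::granges(regions)))
  gaps <- placement_gaps(genome, excluded)
  widths <- BiocGenerics::width(regions)
  chrom_ids <- stats::setNames(seq_along(genome$chrom_sizes),
                               names(genome$chrom_sizes))
  gaps$chrom_id <- chrom_ids[gaps$chrom]
  f_chr <- chrom_ids[as.character(GenomeInfoDb::seqnames(features))]
  f_s <- BiocGenerics::start(features); f_e <- BiocGenerics::end(features)

  null_raw <- with_seed(seed, {
    # draw all permutations up front: per region, n_perm placements
    starts <- matrix(0, nrow = length(regions), ncol = n_perm)
    chrs <- matrix(0L, nrow = length(regions), ncol = n_perm)
    for (i in seq_along(regions)) {
      pl <- sample_placements(gaps, widths[i], n_perm)
      if (is.null(pl))
        stop(sprintf("no valid placement for region %d (width %d bp)",
                     i, widths[i]), call. = FALSE)
      starts[i, ] <- pl$start
      chrs[i, ] <- chrom_ids[pl$chrom]
    }
    vapply(seq_len(n_perm), function(p) {
      count_hits_num(f_chr, f_s, f_e,
                     chrs[, p], starts[, p], starts[, p] + widths - 1)
    }, numeric(1))
  })
  null_norm <- null_raw / region_set_bp * 1e7
  null_mean <- mean(null_norm)
  null_sd <- stats::sd(null_norm)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (!degenerate) (obs_norm - null_mean) / null_sd
       else if (obs_norm == null_mean) 0 else sign(obs_norm - null_mean) * Inf
  p_emp <- (1 + sum(null_raw >= obs_raw)) / (1 + n_perm)
  structure(list(observed_norm = obs_norm, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_empirical = p_emp,
                 n_perm = as.integer(n_perm), region_set_bp = region_set_bp,
                 observed_raw = obs_raw, degenerate_null = degenerate,
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d features in %s bp (%.3f per 10 Mb); null %.3f +/- %.3f; z = %.2f, p = %.4g (%d perms)\n",
    x$observed_raw, format(x$region_set_bp, big.mark = ","), x$observed_norm,
    x$null_mean, x$null_sd, x$z, x$p_empirical, x$n_perm))
  invisible(x)
}

#' Per-pattern enrichment table
#'
#' Runs [permutation_test()] independently for each labelled region set
#' (e.g., SE, SE1, SE2, SE3, TE) against the same features. No
#' cross-pattern multiplicity correction is applied to the primary
#' z / p columns; a Bonferroni-adjusted empirical p is emitted alongside
#' for transparency.
#'
#' @param features `GRanges` of query features.
#' @param region_sets Named list of `GRanges` region sets.
#' @param genome An [se_genome()].
#' @param n_perm Permutations per set (default 1000).
#' @param seed Optional base seed; set `i` uses `seed + i`.
#' @return A data.frame with one row per non-empty set: label,
#'   `observed_raw`, `observed_norm`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical`, `p_bonferroni`, `region_set_bp`, `significant`
#'   (|z| > 1.96).
#' @export
enrichment_by_pattern <- function(features, region_sets, genome,
                                  n_perm = 1000, seed = NULL) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  empty <- vapply(region_sets, length, integer(1)) == 0
  if (any(empty))
    warning("skipping empty region set(s): ",
            paste(names(region_sets)[empty], collapse = ", "), call. = FALSE)
  region_sets <- region_sets[!empty]
  n_tests <- length(region_sets)
  rows <- lapply(seq_along(region_sets), function(i) {
    r <- permutation_test(features, region_sets[[i]], genome, n_perm = n_perm,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(label = names(region_sets)[i],
               observed_raw = r$observed_raw,
               observed_norm = r$observed_norm,
               null_mean = r$null_mean, null_sd = r$null_sd,
               z = r$z, p_empirical = r$p_empirical,
               p_bonferroni = min(1, r$p_empirical * n_tests),
               region_set_bp = r$region_set_bp,
               significant = (is.finite(r$z) & abs(r$z) > 1.96) | is.infinite(r$z),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
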
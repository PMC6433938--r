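#' Filter genes by counts-per-million expression
#'
#' Computes CPM per sample (`counts / column_total * 1e6`, via
#' `edgeR::cpm`) and retains genes with CPM above `threshold` in at least
#' `min_samples` samples — the standard lowly-expressed-gene filter before
#' differential expression.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param threshold CPM threshold (default 0.5, strict inequality).
#' @param min_samples Minimum number of samples above threshold (default 2).
#' @return A list: `genes` (retained rownames), `keep` (logical per input
#'   gene), `cpm` (CPM matrix of retained genes), `cpm_all` (full CPM
#'   matrix).
#' @export
cpm_filter <- function(counts, threshold = 0.5, min_samples = 2) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cpm <- edgeR::cpm(counts)
  keep <- rowSums(cpm > threshold) >= min_samples
  list(genes = rownames(counts)[keep], keep = keep,
       cpm = cpm[keep, , drop = FALSE], cpm_all = cpm)
}

#' Simple two-group differential expression on CPM
#'
#' A transparent two-group stand-in for a full linear-model DE fit:
#' `log2fc` is the difference of group means of `log2(CPM + 0.5)`
#' (stimulated minus vehicle), `ave_expr` the grand mean, and the p-value a
#' two-sided Welch t-test per gene. Flags follow the conventional
#' thresholds: `significant` when `p < 0.05` and `|log2fc| >= 1`;
#' `highly_expressed` when `ave_expr > 5`. A precomputed DE table can
#' bypass this entirely; see [de_flags()].
#'
#' @param cpm CPM matrix (genes x samples), e.g. from [cpm_filter()].
#' @param groups Factor/character per sample with exactly two levels.
#' @param stimulated Level treated as the stimulated condition (default the
#'   second level).
#' @param p_threshold,lfc_threshold,high_expr_threshold Flag thresholds
#'   (defaults 0.05, 1, 5).
#' @return A data.frame with `gene`, `log2fc`, `ave_expr`, `p_value`,
#'   `significant`, `highly_expressed`.
#' @export
simple_de <- function(cpm, groups, stimulated = NULL,
                      p_threshold = 0.05, lfc_threshold = 1,
                      high_expr_threshold = 5) {
  cpm <- as.matrix(cpm)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(cpm), nlevels(groups) == 2)
  if (any(table(groups) < 2))
    stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(stimulated)) stimulated <- levels(groups)[2]
  stopifnot(stimulated %in% levels(groups))
  x <- log2(cpm + 0.5)
  a <- x[, groups == stimulated, drop = FALSE]
  b <- x[, groups != stimulated, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  na <- ncol(a); nb <- ncol(b)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  lfc <- ma - mb
  # zero within-group variance: the t statistic is undefined; call the
  # degenerate cases directly (no difference -> 1, perfect separation -> 0)
  p[se2 == 0 & lfc == 0] <- 1
  p[se2 == 0 & lfc != 0] <- 0
  ave <- rowMeans(x)
  data.frame(gene = if (!is.null(rownames(cpm))) rownames(cpm)
             else as.character(seq_len(nrow(cpm))),
             log2fc = lfc, ave_expr = ave, p_value = p,
             significant = p < p_threshold & abs(lfc) >= lfc_threshold,
             highly_expressed = ave > high_expr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recompute significance flags on a supplied DE table
#'
#' Applies the threshold rules (`p < 0.05` and `|log2fc| >= 1`;
#' `ave_expr > 5`) to any table with `log2fc`, `ave_expr`, `p_value`
#' columns, e.g. one produced upstream by a full linear-model fit.
#'
#' @param de data.frame with columns `gene`, `log2fc`, `ave_expr`,
#'   `p_value`.
#' @param p_threshold,lfc_threshold,high_expr_threshold Thresholds
#'   (defaults 0.05, 1, 5).
#' @return The table with `significant` and `highly_expressed` recomputed.
#' @export
de_flags <- function(de, p_threshold = 0.05, lfc_threshold = 1,
                     high_expr_threshold = 5) {
  stopifnot(all(c("log2fc", "ave_expr", "p_value") %in% names(de)))
  de$significant <- de$p_value < p_threshold & abs(de$log2fc) >= lfc_threshold
  de$highly_expressed <- de$ave_expr > high_expr_threshold
  de
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Omnibus Kruskal-Wallis test (tie-corrected, via `stats::kruskal.test`)
#' followed by Dunn's pairwise z tests on the pooled ranks with the
#' tie-corrected variance, Bonferroni-adjusted over all pairs:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups. Ties receive average ranks.
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups).
#' @return A list of class `group_comparison`: `kw_statistic`, `kw_p`,
#'   `pairwise` (data.frame: group1, group2, z, p_raw, p_adjusted),
#'   `n_comparisons`.
#' @export
kruskal_dunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) > 0))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  if (length(unique(values)) == 1) {
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p_raw = 1, p_adjusted = 1,
                     stringsAsFactors = FALSE)
    return(structure(list(kw_statistic = 0, kw_p = 1, pairwise = pw,
                          n_comparisons = n_pairs),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(values, labels)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, labels, mean)
  nn <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  z <- vapply(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    (rbar[[i]] - rbar[[j]]) / sqrt(sigma2 * (1 / nn[[i]] + 1 / nn[[j]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                   p_raw = p_raw,
                   p_adjusted = pmin(1, p_raw * n_pairs),
                   stringsAsFactors = FALSE)
  structure(list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
                 pairwise = pw, n_comparisons = n_pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: Kruskal-Wallis H = %.3f, p = %.4g; %d pairwise Dunn tests (Bonferroni)\n",
              x$kw_statistic, x$kw_p, x$n_comparisons))
  print(x$pairwise)
  invisible(x)
}

#' Pearson correlation of paired log2 binding densities
#'
#' Pearson product-moment correlation between two vectors of per-region
#' log2(rpm/bp) densities with a t-distributed p-value and Bonferroni
#' adjustment over `n_tests` comparisons. Densities should be transformed
#' with [log2_density()] first so zero densities stay finite.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @param n_tests Number of correlations in the family (default 1).
#' @return A list: `r`, `p_raw`, `p_adjusted`, `n`, `degenerate` (TRUE when
#'   either vector has zero variance, in which case `r` is `NA`).
#' @export
density_correlation <- function(x, y, n_tests = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
                n = length(x), degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_raw = ct$p.value,
       p_adjusted = min(1, ct$p.value * n_tests), n = length(x),
       degenerate = FALSE)
}

#' Floored log2 transform for rpm/bp densities
#' @param d Numeric densities.
#' @param eps Floor in rpm/bp applied before log2 (default 0.001) so that
#'   zero-density regions stay finite.
#' @return `log2(pmax(d, eps))`.
#' @export
log2_density <- function(d, eps = 0.001) log2(pmax(d, eps))

#' GC content of regions from a genome sequence
#'
#' Fraction `(G + C) / (A + C + G + T)` per region, case-insensitive, with
#' ambiguous bases (N) excluded from the denominator; an all-N region is
#' `NA`.
#'
#' @param regions `GRanges` within the sequence bounds.
#' @param sequences A `DNAStringSet` named by chromosome (e.g. from
#'   `Biostrings::readDNAStringSet`).
#' @return Numeric vector of GC fractions in \[0, 1\] (or `NA`).
#' @export
gc_content <- function(regions, sequences) {
  if (length(regions) == 0) return(numeric(0))
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  stopifnot(all(chroms %in% names(sequences)))
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i) {
    Biostrings::subseq(sequences[[chroms[i]]],
                       start = BiocGenerics::start(regions)[i],
                       end = BiocGenerics::end(regions)[i])
  }))
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- (freq[, "G"] + freq[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  unname(gc)
}
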
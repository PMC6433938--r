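#' Link genes to their closest super-enhancers within a window
#'
#' For each gene, finds the super-enhancer(s) minimising edge-to-edge
#' distance between gene body and SE span (0 when they overlap), keeping
#' links with distance at most `window` bp. Ties yield multiple links
#' rather than an arbitrary winner, so downstream gene sets are
#' order-independent. Distance follows `bedtools closest` semantics: the
#' number of bases strictly between the two intervals.
#'
#' @param genes `GRanges` of gene bodies with a `name` column.
#' @param ses `GRanges` of super-enhancer regions.
#' @param window Maximum link distance in bp (default 50000).
#' @return A data.frame with columns `gene`, `gene_index`, `se_index`,
#'   `se_region`, `distance`, plus `pattern` when `ses` carries one.
#' @export
closest_within <- function(genes, ses, window = 50000) {
  stopifnot_scalar_number(window, "window", min = 0)
  empty <- data.frame(gene = character(0), gene_index = integer(0),
                      se_index = integer(0), se_region = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (length(genes) == 0 || length(ses) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(genes, ses, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(genes[q], ses[s], ignore.strand = TRUE)
  # keep, per gene, only the minimum-distance SE(s)
  dmin <- tapply(d, q, min)
  keep <- d == dmin[as.character(q)]
  q <- q[keep]; s <- s[keep]; d <- d[keep]
  out <- data.frame(
    gene = if (!is.null(genes$name)) genes$name[q] else as.character(q),
    gene_index = q, se_index = s,
    se_region = sprintf("%s:%d-%d",
                        as.character(GenomeInfoDb::seqnames(ses))[s],
                        BiocGenerics::start(ses)[s], BiocGenerics::end(ses)[s]),
    distance = as.numeric(d), stringsAsFactors = FALSE)
  if (!is.null(ses$pattern)) out$pattern <- as.character(ses$pattern)[s]
  out[order(out$gene_index, out$se_index), , drop = FALSE]
}

#' Flag intervals within a window of any SNP
#'
#' Flags each input interval overlapping the window `snp +/- window` of at
#' least one SNP — the "risk region" convention of tag SNP plus flank. With
#' `window = 0` this reduces to plain overlap.
#'
#' @param regions `GRanges` to flag (genes or SEs).
#' @param snps `GRanges` of SNP positions (1-bp intervals).
#' @param window Flank in bp on each side of the SNP (default 500000).
#' @return Logical vector, one flag per region.
#' @export
snp_proximity <- function(regions, snps, window = 500000) {
  stopifnot_scalar_number(window, "window", min = 0)
  if (length(snps) == 0 || length(regions) == 0)
    return(rep(FALSE, length(regions)))
  expanded <- suppressWarnings(snps + window)
  expanded <- IRanges::restrict(expanded, start = 1L)
  IRanges::overlapsAny(regions, expanded, ignore.strand = TRUE)
}

#' Merge the top-k genes of several ranked correlation lists
#'
#' Builds a gene set as the union of the top `k` symbols of each ranked
#' list (each a data.frame with columns `gene` and `correlation`, sorted by
#' descending correlation) — the construction used for signature sets
#' merged from the top genes of several cohorts.
#'
#' @param ranked_lists Named list of data.frames (`gene`, `correlation`),
#'   each sorted descending and deduplicated.
#' @param k Genes taken from the top of each list (default 200).
#' @param name Name for the resulting set.
#' @return An object of class `gene_set`: `name`, `members` (unique
#'   character vector), `provenance` (per-list origin of each member).
#' @export
merge_top_k_sets <- function(ranked_lists, k = 200, name = "merged_top_k") {
  stopifnot_scalar_number(k, "k", min = 1)
  stopifnot(is.list(ranked_lists), length(ranked_lists) >= 1)
  if (is.null(names(ranked_lists)))
    names(ranked_lists) <- paste0("list_", seq_along(ranked_lists))
  tops <- lapply(names(ranked_lists), function(nm) {
    df <- ranked_lists[[nm]]
    stopifnot(all(c("gene", "correlation") %in% names(df)))
    if (anyDuplicated(df$gene))
      stop("duplicate genes in ranked list '", nm, "'", call. = FALSE)
    if (is.unsorted(rev(df$correlation)))
      stop("ranked list '", nm, "' is not sorted by descending correlation",
           call. = FALSE)
    if (nrow(df) < k)
      warning(sprintf("list '%s' has only %d genes (< k = %d); using all",
                      nm, nrow(df), k), call. = FALSE)
    utils::head(df$gene, k)
  })
  members <- unique(unlist(tops))
  prov <- vapply(members, function(g) {
    paste(names(ranked_lists)[vapply(tops, function(t) g %in% t, logical(1))],
          collapse = ",")
  }, character(1))
  structure(list(name = name, members = members,
                 provenance = prov), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}
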
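#' Merge intervals lying within a maximum gap of each other
#'
#' Transitively merges intervals on the same chromosome whose gap is at most
#' `max_gap` bases (a gap equal to `max_gap` merges; one base more does
#' not). Strand is ignored, as enhancer calls are unstranded. This is the
#' substrate for ROSE-style peak stitching.
#'
#' @param gr A `GRanges`.
#' @param max_gap Maximum gap in bp (>= 0); 0 merges only overlapping or
#'   book-ended intervals.
#' @param with_revmap Keep a `revmap` column mapping each merged interval to
#'   the input indices it absorbed?
#' @return A sorted `GRanges` of disjoint merged intervals.
#' @export
merge_overlapping <- function(gr, max_gap = 0, with_revmap = FALSE) {
  stopifnot_scalar_number(max_gap, "max_gap", min = 0)
  GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                        ignore.strand = TRUE, with.revmap = with_revmap)
}

#' Drop peaks overlapping a blacklist
#'
#' Removes every peak sharing at least one base with any blacklist interval
#' (the standard pre-filter against regions of anomalous signal). Input
#' order is preserved.
#'
#' @param peaks A `GRanges` of peaks.
#' @param blacklist A `GRanges` of blacklist regions.
#' @return The retained subset of `peaks`.
#' @export
remove_blacklisted <- function(peaks, blacklist) {
  if (length(blacklist) == 0 || length(peaks) == 0) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

#' Do two intervals share at least one base?
#'
#' Overlap requires >= 1 shared base: half-open adjacency (BED `a.end ==
#' b.start`) is not overlap, matching `bedtools intersect` defaults.
#' Chromosome comparison is exact-string; strand is ignored.
#'
#' @param a,b `GRanges` of length 1 (or equal lengths, compared pairwise).
#' @return Logical.
#' @export
overlap_any <- function(a, b) {
  as.logical(IRanges::poverlaps(GenomicRanges::granges(a),
                                GenomicRanges::granges(b),
                                ignore.strand = TRUE))
}
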
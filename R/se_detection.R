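#' Remove peaks overlapping promoter windows
#'
#' Drops every peak overlapping the window of `tss_flank` bp on each side of
#' any transcription start site (gene start on the + strand, gene end on the
#' - strand; unstranded genes are treated as +). Applied before stitching,
#' mirroring the ROSE `-t` option with its 2 kb default.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes `GRanges` of gene bodies (strand-aware; see [read_genes()]).
#' @param tss_flank Flank in bp on each side of the TSS (default 2000).
#' @return The retained subset of `peaks`.
#' @export
exclude_promoters <- function(peaks, genes, tss_flank = 2000) {
  stopifnot_scalar_number(tss_flank, "tss_flank", min = 0)
  if (length(genes) == 0 || length(peaks) == 0) return(peaks)
  prom <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = tss_flank, downstream = tss_flank))
  prom <- IRanges::restrict(prom, start = 1L)
  peaks[!IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)]
}

#' Stitch peaks into candidate enhancer regions
#'
#' Merges peaks lying within `stitch_distance` bp of each other into
#' stitched enhancer regions spanning min(start) to max(end) of their
#' constituents (the ROSE `-s` stitching step; the default 12.5 kb is the
#' standard parameterisation).
#'
#' @param peaks `GRanges` of (promoter-excluded, blacklist-filtered) peaks.
#' @param stitch_distance Maximum gap in bp joining two peaks (default 12500).
#' @return A sorted `GRanges` of stitched regions with metadata columns
#'   `n_constituents` and `revmap` (indices of constituent peaks in the
#'   input).
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  stopifnot_scalar_number(stitch_distance, "stitch_distance", min = 0)
  if (length(peaks) == 0)
    return(GenomicRanges::GRanges(n_constituents = integer(0)))
  st <- merge_overlapping(peaks, max_gap = stitch_distance)
  # constituents are exactly the peaks contained in each merged region
  h <- GenomicRanges::findOverlaps(peaks, st, ignore.strand = TRUE)
  rv <- S4Vectors::splitAsList(
    S4Vectors::queryHits(h),
    factor(S4Vectors::subjectHits(h), levels = seq_along(st)))
  S4Vectors::mcols(st) <- S4Vectors::DataFrame(revmap = unname(rv),
                                               n_constituents = unname(lengths(rv)))
  st
}

#' Background-normalised signal density over regions
#'
#' Computes reads per million mapped reads per base pair (rpm/bp) over each
#' region from a piecewise-constant coverage track:
#' `(mean per-base coverage over the region) / (total_mapped_reads / 1e6)`.
#' The track is expected to come from 200 bp-extended reads; extension is
#' the track producer's responsibility. Bases absent from the track count
#' as zero coverage.
#'
#' @param regions `GRanges` of regions to quantify.
#' @param coverage `GRanges` coverage track with a numeric `score` column
#'   (as from [read_bedgraph()]).
#' @param total_mapped_reads Library size used for the per-million scaling.
#' @return Numeric vector of rpm/bp values, one per region.
#' @export
coverage_density <- function(regions, coverage, total_mapped_reads) {
  stopifnot_scalar_number(total_mapped_reads, "total_mapped_reads", min = 1)
  if (length(regions) == 0) return(numeric(0))
  sums <- numeric(length(regions))
  if (length(coverage) > 0) {
    hits <- GenomicRanges::findOverlaps(regions, coverage, ignore.strand = TRUE)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- pmin(BiocGenerics::end(regions)[q], BiocGenerics::end(coverage)[s]) -
        pmax(BiocGenerics::start(regions)[q], BiocGenerics::start(coverage)[s]) + 1
      contrib <- ov * coverage$score[s]
      sums <- as.numeric(tapply(contrib, factor(q, levels = seq_along(regions)), sum,
                                default = 0))
    }
  }
  (sums / BiocGenerics::width(regions)) / (total_mapped_reads / 1e6)
}

#' Slope-1 tangent cutoff on the ranked density curve
#'
#' Sorts densities ascending, rescales ranks to \[0,1\] by `(n-1)` and
#' densities to \[0,1\] by `(max-min)` after subtracting the minimum, and
#' finds the point where the slope of the scaled curve first reaches 1
#' scanning from the low end — the tangent point of a slope-1 line on the
#' signal-density versus density-rank plot. Regions with density strictly
#' greater than the cutoff are super-enhancers; ties go to the typical
#' side (conservative SE calls).
#'
#' The discrete derivative is a centred 3-point finite difference on the
#' scaled curve after a running-mean smoother of window `max(1, n/100)`
#' ranks, which stabilises the crossing on plateaued curves.
#'
#' @param densities Numeric vector of net densities (rpm/bp).
#' @return A list of class `tangent_cutoff`: `cutoff` (density at the
#'   tangent point; `NA` when degenerate), `is_se` (logical per input
#'   density), and `curve` (a data.frame with rank, density, scaled
#'   coordinates and slope for plotting).
#' @export
tangent_cutoff <- function(densities) {
  n <- length(densities)
  degenerate <- n < 3 || !is.finite(max(densities)) ||
    max(densities) == min(densities)
  if (degenerate) {
    return(structure(list(cutoff = NA_real_,
                          is_se = rep(FALSE, n),
                          curve = NULL), class = "tangent_cutoff"))
  }
  ord <- order(densities)
  d <- densities[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (d - d[1]) / (d[n] - d[1])
  w <- max(1L, floor(n / 100))
  ys <- y
  if (w > 1) {
    sm <- stats::filter(y, rep(1 / w, w), sides = 2)
    ys[!is.na(sm)] <- sm[!is.na(sm)]
  }
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  at <- which(slope >= 1)[1]
  if (is.na(at)) at <- which.min(abs(slope - 1))
  cutoff <- d[at]
  structure(list(cutoff = cutoff,
                 is_se = densities > cutoff,
                 curve = data.frame(rank = seq_len(n), density = d,
                                    x_scaled = x, y_scaled = y, slope = slope,
                                    is_se = d > cutoff)),
            class = "tangent_cutoff")
}

#' @export
print.tangent_cutoff <- function(x, ...) {
  cat(sprintf("tangent_cutoff: cutoff = %s; %d SE / %d regions\n",
              format(x$cutoff), sum(x$is_se), length(x$is_se)))
  invisible(x)
}

#' Call super-enhancers from peaks and coverage tracks
#'
#' The full calling pipeline for one condition: blacklist filtering, TSS
#' exclusion, stitching, background-subtracted density quantification over
#' the stitched spans, and the slope-1 tangent split into super-enhancers
#' and typical enhancers. Net density is `max(signal - background, 0)` in
#' rpm/bp; flooring at zero follows the ROSE convention for noise regions
#' where input exceeds signal.
#'
#' @param peaks `GRanges` of TF peaks for the condition.
#' @param signal `GRanges` bedGraph-style coverage track for the TF.
#' @param background Matching input/control coverage track (may be empty).
#' @param genes `GRanges` of gene bodies for TSS exclusion.
#' @param genome An [se_genome()] carrying the blacklist.
#' @param total_reads_signal,total_reads_background Library sizes for the
#'   per-million normalisation of each track.
#' @param tss_flank,stitch_distance Pipeline parameters (defaults 2000 and
#'   12500 bp).
#' @return An object of class `se_partition`: `stitched` (`GRanges` with
#'   `signal_rpm_bp`, `background_rpm_bp`, `net_density`, `is_se`),
#'   `se`/`te` subsets, `cutoff`, `curve`, and the parameters used.
#' @export
call_superenhancers <- function(peaks, signal, background, genes, genome,
                                total_reads_signal = 1e6,
                                total_reads_background = 1e6,
                                tss_flank = 2000, stitch_distance = 12500) {
  stopifnot(inherits(genome, "se_genome"))
  kept <- remove_blacklisted(peaks, genome$blacklist)
  kept <- exclude_promoters(kept, genes, tss_flank = tss_flank)
  st <- stitch(kept, stitch_distance = stitch_distance)
  if (length(st) == 0) {
    empty <- GenomicRanges::GRanges()
    return(structure(list(stitched = st, se = empty, te = empty,
                          cutoff = NA_real_, curve = NULL,
                          params = list(tss_flank = tss_flank,
                                        stitch_distance = stitch_distance)),
                     class = "se_partition"))
  }
  sig <- coverage_density(st, signal, total_reads_signal)
  bg <- if (length(background) > 0)
    coverage_density(st, background, total_reads_background) else numeric(length(st))
  st$signal_rpm_bp <- sig
  st$background_rpm_bp <- bg
  st$net_density <- pmax(sig - bg, 0)
  tc <- tangent_cutoff(st$net_density)
  st$is_se <- tc$is_se
  structure(list(stitched = st,
                 se = st[st$is_se],
                 te = st[!st$is_se],
                 cutoff = tc$cutoff,
                 curve = tc$curve,
                 params = list(tss_flank = tss_flank,
                               stitch_distance = stitch_distance)),
            class = "se_partition")
}

#' @export
print.se_partition <- function(x, ...) {
  cat(sprintf("se_partition: %d stitched regions -> %d SE, %d TE (cutoff %s rpm/bp)\n",
              length(x$stitched), length(x$se), length(x$te), format(x$cutoff)))
  invisible(x)
}
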
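#' Label binding sites as primary, persistent or secondary
#'
#' Compares TF binding sites before and after stimulation. A before-peak
#' sharing at least one base with any after-peak is PERSISTENT (as is its
#' partner); a before-only peak is PRIMARY; an after-only peak is
#' SECONDARY. Persistent sites keep each condition's own coordinates, with
#' partner indices recorded, so downstream overlap counting in a condition
#' uses that condition's intervals.
#'
#' @param before_peaks,after_peaks `GRanges` of blacklist-filtered peaks for
#'   the vehicle and stimulated conditions.
#' @return A list with elements `before` and `after`: each the input
#'   `GRanges` plus metadata columns `label` (factor PRIMARY / PERSISTENT /
#'   SECONDARY) and `partners` (an `IntegerList` of indices into the other
#'   condition; empty for non-persistent sites).
#' @export
label_sites <- function(before_peaks, after_peaks) {
  hits <- GenomicRanges::findOverlaps(before_peaks, after_peaks,
                                      ignore.strand = TRUE)
  b_pers <- unique(S4Vectors::queryHits(hits))
  a_pers <- unique(S4Vectors::subjectHits(hits))
  lv <- c("PRIMARY", "PERSISTENT", "SECONDARY")

  before <- before_peaks
  lab_b <- rep("PRIMARY", length(before_peaks))
  lab_b[b_pers] <- "PERSISTENT"
  before$label <- factor(lab_b, levels = lv)
  before$partners <- S4Vectors::splitAsList(
    S4Vectors::subjectHits(hits),
    factor(S4Vectors::queryHits(hits), levels = seq_along(before_peaks)))

  after <- after_peaks
  lab_a <- rep("SECONDARY", length(after_peaks))
  lab_a[a_pers] <- "PERSISTENT"
  after$label <- factor(lab_a, levels = lv)
  after$partners <- S4Vectors::splitAsList(
    S4Vectors::queryHits(hits),
    factor(S4Vectors::subjectHits(hits), levels = seq_along(after_peaks)))

  list(before = before, after = after)
}

#' Classify super-enhancers into SE1-SE6 patterns
#'
#' Counts labelled binding sites overlapping each SE and assigns the
#' dynamics pattern. After-stimulation SEs overlapping persistent sites
#' only are SE1, secondary only SE3, both SE2; before-stimulation SEs
#' overlapping persistent only are SE4, primary only SE6, both SE5. An SE
#' overlapping no labelled site is UNBOUND (possible when SEs are called
#' from a different mark than the labelled TF).
#'
#' @param ses `GRanges` of super-enhancer regions for one condition.
#' @param labeled `GRanges` of labelled peaks for the *same* condition, as
#'   returned by [label_sites()] (`$after` for `condition = "after"`).
#' @param condition `"before"` or `"after"`.
#' @return `ses` with metadata columns `n_persistent`, `n_primary`,
#'   `n_secondary` and `pattern` (factor with levels SE1..SE6, UNBOUND).
#' @export
classify_se <- function(ses, labeled, condition = c("after", "before")) {
  condition <- match.arg(condition)
  count_label <- function(lab) {
    sel <- labeled[labeled$label == lab]
    if (length(sel) == 0) integer(length(ses))
    else GenomicRanges::countOverlaps(ses, sel, ignore.strand = TRUE)
  }
  n_pers <- count_label("PERSISTENT")
  n_prim <- count_label("PRIMARY")
  n_sec <- count_label("SECONDARY")
  pattern <- rep("UNBOUND", length(ses))
  if (condition == "after") {
    pattern[n_pers > 0 & n_sec == 0] <- "SE1"
    pattern[n_pers > 0 & n_sec > 0] <- "SE2"
    pattern[n_pers == 0 & n_sec > 0] <- "SE3"
  } else {
    pattern[n_pers > 0 & n_prim == 0] <- "SE4"
    pattern[n_pers > 0 & n_prim > 0] <- "SE5"
    pattern[n_pers == 0 & n_prim > 0] <- "SE6"
  }
  ses$n_persistent <- n_pers
  ses$n_primary <- n_prim
  ses$n_secondary <- n_sec
  ses$pattern <- factor(pattern, levels = se_pattern_levels())
  ses$condition <- rep(condition, length(ses))
  ses
}

#' Pattern factor levels used throughout
#' @return Character vector `SE1..SE6, UNBOUND`.
#' @export
se_pattern_levels <- function() c(paste0("SE", 1:6), "UNBOUND")

#' Track before-to-after fates of super-enhancers
#'
#' For each classified before-stimulation SE, finds after-stimulation SEs
#' overlapping it by at least one base. An SE with no overlap is `lost`.
#' Otherwise the fate is `persists_as` when the after pattern is the
#' expected continuation of the before pattern (SE4 to SE1; SE5 to SE1 or
#' SE2; SE6 to SE3) and `reclassified_as` when the pattern class changed
#' (e.g., an SE4 region that initiated secondary binding becomes SE2). A
#' before-SE overlapping several after-SEs yields one record per overlap,
#' flagged as multi-mapping.
#'
#' @param before_ses,after_ses Classified `GRanges` from [classify_se()].
#' @return A data.frame with one row per (before-SE, after-SE) pair (or per
#'   lost before-SE): coordinates, `before_pattern`, `after_pattern`,
#'   `fate`, `multi_mapping`.
#' @export
transitions <- function(before_ses, after_ses) {
  stopifnot(!is.null(before_ses$pattern))
  n_b <- length(before_ses)
  coords <- function(gr, i) sprintf("%s:%d-%d",
                                    as.character(GenomeInfoDb::seqnames(gr))[i],
                                    BiocGenerics::start(gr)[i],
                                    BiocGenerics::end(gr)[i])
  hits <- GenomicRanges::findOverlaps(before_ses, after_ses, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  n_matches <- GenomicRanges::countOverlaps(before_ses, after_ses,
                                            ignore.strand = TRUE)
  persists <- function(bp, ap) {
    (bp == "SE4" & ap == "SE1") |
      (bp == "SE5" & ap %in% c("SE1", "SE2")) |
      (bp == "SE6" & ap == "SE3")
  }
  rows <- list()
  if (length(hits) > 0) {
    bp <- as.character(before_ses$pattern)[q]
    ap <- as.character(after_ses$pattern)[s]
    rows[[1]] <- data.frame(
      before_index = q, before_region = coords(before_ses, q),
      before_pattern = bp,
      after_index = s, after_region = coords(after_ses, s),
      after_pattern = ap,
      fate = ifelse(persists(bp, ap), "persists_as", "reclassified_as"),
      multi_mapping = n_matches[q] > 1,
      stringsAsFactors = FALSE)
  }
  lost <- setdiff(seq_len(n_b), unique(q))
  if (length(lost) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      before_index = lost, before_region = coords(before_ses, lost),
      before_pattern = as.character(before_ses$pattern)[lost],
      after_index = NA_integer_, after_region = NA_character_,
      after_pattern = NA_character_,
      fate = "lost", multi_mapping = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(before_index = integer(0), before_region = character(0),
                      before_pattern = character(0), after_index = integer(0),
                      after_region = character(0), after_pattern = character(0),
                      fate = character(0), multi_mapping = logical(0))
  out[order(out$before_index, out$after_index), , drop = FALSE]
}

#' Count super-enhancers per dynamics pattern
#'
#' @param patterns Factor/character vector of patterns, or a classified
#'   `GRanges` from [classify_se()].
#' @return A named integer vector over SE1..SE6 and UNBOUND, summing to the
#'   number of inputs.
#' @export
pattern_census <- function(patterns) {
  if (inherits(patterns, "GRanges")) patterns <- patterns$pattern
  tab <- table(factor(patterns, levels = se_pattern_levels()))
  stats::setNames(as.integer(tab), names(tab))
}
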
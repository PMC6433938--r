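#' Read a BED-family peak file as a GRanges
#'
#' Parses BED3, BED6 or ENCODE narrowPeak into a `GRanges`. On-disk BED
#' coordinates are 0-based half-open; the returned `GRanges` follows the
#' usual Bioconductor 1-based closed convention (the conversion happens on
#' read, so a line `chr1 100 200` becomes `chr1:101-200`, 100 bp).
#'
#' @param path Path to an uncompressed tab-separated BED/narrowPeak file.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`. For narrowPeak
#'   the 10th column is kept as `summit_offset` (0-based offset of the summit
#'   from the region start; `-1` in the file becomes `NA`).
#' @return A `GRanges`, in file order, with metadata columns `name`, `score`
#'   and (narrowPeak only) `signalValue` and `summit_offset`.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ncol_min <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_min)
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d of %s: expected >= %d tab-separated fields, found %d",
                 bad[1], path, ncol_min, nf[bad[1]]), call. = FALSE)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  start0 <- suppressWarnings(as.numeric(col(2)))
  end0 <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d of %s: non-numeric coordinates", bad[1], path),
         call. = FALSE)
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad) > 0)
    stop(sprintf("validation error at line %d of %s: requires 0 <= start < end (got %s >= %s)",
                 bad[1], path, col(2)[bad[1]], col(3)[bad[1]]), call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (dialect != "bed3") {
    gr$name <- col(4)
    gr$score <- suppressWarnings(as.numeric(col(5)))
    strand <- col(6)
    strand[!strand %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- strand
  }
  if (dialect == "narrowPeak") {
    gr$signalValue <- suppressWarnings(as.numeric(col(7)))
    summit <- suppressWarnings(as.integer(col(10)))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= BiocGenerics::width(gr))
    if (length(bad) > 0)
      stop(sprintf("validation error at line %d of %s: summit offset outside peak",
                   bad[1], path), call. = FALSE)
    gr$summit_offset <- summit
  }
  gr
}

#' Write a GRanges as a sorted BED file
#'
#' Emits tab-separated, newline-terminated BED (0-based half-open) sorted by
#' (chrom, start, end). With `keep_mcols = TRUE`, `name` and `score` columns
#' are written as BED6.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param keep_mcols Write name/score/strand columns (BED6)?
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, keep_mcols = FALSE) {
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr))
  if (keep_mcols) {
    df$name <- if (!is.null(gr$name)) gr$name else paste0("region_", seq_along(gr))
    df$score <- if (!is.null(gr$score)) gr$score else 0
    df$strand <- sub("\\*", ".", as.character(BiocGenerics::strand(gr)))
  }
  write_plain(df, path)
}

#' Read a 4-column bedGraph coverage track
#'
#' @param path Path to an uncompressed bedGraph (chrom, start, end, value;
#'   0-based half-open on disk).
#' @return A `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a piecewise-constant coverage track as bedGraph
#' @param gr A `GRanges` with a `score` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(gr, path) {
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   score = gr$score)
  write_plain(df, path)
}

#' Read a two-column chrom.sizes file
#' @param path Path to a tab-separated chromosome/length table.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Read gene models from GTF or a 5-column TSV
#'
#' `read_genes()` accepts either a GTF (gene records only are kept; 1-based
#' closed coordinates as per the format) or a header-less 5-column TSV
#' `name, chrom, start, end, strand` with BED-style 0-based half-open
#' coordinates, which the synthetic generator writes.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"tsv"`; default guesses from the extension.
#' @return A `GRanges` of gene bodies with a `name` metadata column.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "tsv"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[gr$type == "gene"]
    nm <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    gr2 <- GenomicRanges::granges(gr)
    gr2$name <- nm
    return(gr2)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "chrom", "start", "end", "strand"),
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character"))
  if (any(df$start >= df$end))
    stop("validation error: gene with start >= end in ", path, call. = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end),
                               strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  gr$name <- df$name
  gr
}

#' Bundle chromosome sizes and a blacklist into a genome description
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param blacklist `GRanges` of regions excluded from peaks and from
#'   permutation placements (may be empty).
#' @return An object of class `se_genome`.
#' @export
se_genome <- function(chrom_sizes, blacklist = GenomicRanges::GRanges()) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0))
  bl_chr <- as.character(GenomeInfoDb::seqnames(blacklist))
  if (length(blacklist) > 0) {
    if (!all(bl_chr %in% names(chrom_sizes)))
      stop("blacklist interval on unknown chromosome", call. = FALSE)
    if (any(BiocGenerics::end(blacklist) > chrom_sizes[bl_chr]))
      stop("blacklist interval extends beyond its chromosome", call. = FALSE)
  }
  structure(list(chrom_sizes = chrom_sizes, blacklist = blacklist),
            class = "se_genome")
}

#' @export
print.se_genome <- function(x, ...) {
  cat(sprintf("se_genome: %d chromosome(s), %.1f Mb total, %d blacklist region(s)\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6, length(x$blacklist)))
  invisible(x)
}
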
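# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# write.table without scientific notation for large coordinates
write_plain <- function(df, path, col.names = FALSE) {
  old <- options(scipen = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  invisible(x)
}

#' Warn about chromosome names present in only one of two range sets
#'
#' Chromosome matching throughout the package is exact-string: no "chr"
#' prefix normalisation is attempted, because silent renaming hides data
#' errors. This helper surfaces likely naming mismatches.
#'
#' @param a,b `GRanges` objects (or anything with `seqnames`).
#' @param labels Character vector of length 2 naming the two inputs in the
#'   warning message.
#' @return Invisibly, the character vector of non-shared chromosome names.
#' @export
check_chrom_names <- function(a, b, labels = c("a", "b")) {
  ca <- unique(as.character(GenomeInfoDb::seqnames(a)))
  cb <- unique(as.character(GenomeInfoDb::seqnames(b)))
  only <- c(setdiff(ca, cb), setdiff(cb, ca))
  if (length(only) > 0)
    warning(sprintf(
      "chromosome names present in only one input (%s vs %s): %s",
      labels[1], labels[2], paste(only, collapse = ", ")), call. = FALSE)
  invisible(only)
}
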
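#' Weighted running-sum enrichment score
#'
#' Walks a ranked gene list (scores non-increasing) and accumulates a
#' running sum that increments by `|score|^weight / sum_hits |score|^weight`
#' at gene-set members and decrements by `1 / (N - N_hits)` elsewhere. The
#' enrichment score (ES) is the signed value of the running sum at its
#' maximal absolute deviation from zero. `weight = 0` gives the classic
#' (Kolmogorov-Smirnov-like) statistic, under which the running sum
#' telescopes back to zero; `weight = 1` is the standard weighted form.
#'
#' @param genes Character vector of unique gene symbols, ranked best-first.
#' @param scores Numeric ranking metric, same length, sorted non-increasing
#'   (e.g., log2 fold change or average log2 expression, high to low).
#' @param gene_set Character vector (or [merge_top_k_sets()] `gene_set`) of
#'   member symbols; must intersect the ranking and be a proper subset.
#' @param weight Exponent on `|score|` for hit increments (default 1).
#' @return A list: `es`, `running` (numeric, length N), `peak_index`,
#'   `hit_indices`.
#' @export
enrichment_score <- function(genes, scores, gene_set, weight = 1) {
  if (inherits(gene_set, "gene_set")) gene_set <- gene_set$members
  N <- length(genes)
  stopifnot(length(scores) == N, weight >= 0)
  if (anyDuplicated(genes) > 0) stop("ranked genes must be unique", call. = FALSE)
  if (is.unsorted(rev(scores)))
    stop("scores must be sorted non-increasing", call. = FALSE)
  hit <- genes %in% gene_set
  n_hits <- sum(hit)
  if (n_hits == 0) stop("gene set is disjoint from the ranking", call. = FALSE)
  if (n_hits == N)
    stop("gene set covers the entire ranking (miss denominator is zero)",
         call. = FALSE)
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, n_hits)  # all-zero scores: fall back to equal weights
  step <- numeric(N)
  step[hit] <- w / sum(w)
  step[!hit] <- -1 / (N - n_hits)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak_index = peak,
       hit_indices = which(hit))
}

#' Permutation significance for a gene-set enrichment score
#'
#' Null distribution by gene-tag permutation: `n_perm` random subsets of
#' the ranking with the same size as the observed overlap, each scored
#' with [enrichment_score()] (the only permutation scheme available to
#' pre-ranked GSEA). Reports a two-sided permutation p
#' `(1 + #\{|es_perm| >= |es|\}) / (1 + n_perm)`, a one-sided variant for
#' the observed sign, and `nes = es / mean(|es_perm|)` over permutations
#' matching the observed sign.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed; results are deterministic given it.
#' @return An object of class `gsea_result`: `es`, `nes`, `p_perm`
#'   (two-sided), `p_one_sided`, `leading_edge` (character vector),
#'   `peak_index`, `running`, `n_perm`, `weight`, `seed`.
#' @export
gsea_test <- function(genes, scores, gene_set, weight = 1, n_perm = 1000,
                      seed = NULL) {
  if (inherits(gene_set, "gene_set")) gene_set <- gene_set$members
  obs <- enrichment_score(genes, scores, gene_set, weight = weight)
  n_hits <- length(obs$hit_indices)
  N <- length(genes)
  es_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, n_hits)
    enrichment_score(genes, scores, genes[idx], weight = weight)$es
  }, numeric(1)))
  p_two <- (1 + sum(abs(es_perm) >= abs(obs$es))) / (1 + n_perm)
  same_sign <- if (obs$es >= 0) es_perm >= obs$es else es_perm <= obs$es
  p_one <- (1 + sum(same_sign)) / (1 + n_perm)
  matching <- if (obs$es >= 0) es_perm[es_perm > 0] else es_perm[es_perm < 0]
  nes <- if (length(matching) > 0) obs$es / mean(abs(matching)) else NA_real_
  le <- leading_edge(obs$running, obs$peak_index, genes, gene_set)
  structure(list(es = obs$es, nes = nes, p_perm = p_two, p_one_sided = p_one,
                 leading_edge = le$genes, leading_edge_trailing = le$trailing,
                 peak_index = obs$peak_index, running = obs$running,
                 n_perm = as.integer(n_perm), weight = weight, seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.3f (NES = %.3f), p = %.4g (%d perms, weight %g); leading edge %d genes\n",
              x$es, x$nes, x$p_perm, x$n_perm, x$weight,
              length(x$leading_edge)))
  invisible(x)
}

#' Leading-edge genes of an enrichment score
#'
#' Gene-set members at ranks up to the running-sum peak when the ES is
#' positive. For a negative ES the trailing-edge analogue (members at ranks
#' at or after the peak) is returned, flagged as such.
#'
#' @param running Running sum from [enrichment_score()].
#' @param peak_index Index of the ES extremum.
#' @param genes Ranked gene symbols.
#' @param gene_set Member symbols.
#' @return A list: `genes` (character), `trailing` (logical; TRUE when the
#'   ES was negative and the trailing-edge analogue is returned).
#' @export
leading_edge <- function(running, peak_index, genes, gene_set) {
  if (inherits(gene_set, "gene_set")) gene_set <- gene_set$members
  es <- running[peak_index]
  if (es > 0) {
    list(genes = genes[seq_len(peak_index)][genes[seq_len(peak_index)] %in% gene_set],
         trailing = FALSE)
  } else {
    idx <- seq(peak_index, length(genes))
    list(genes = genes[idx][genes[idx] %in% gene_set], trailing = TRUE)
  }
}
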
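# Brute-force oracles, written independently of the implementation paths
# they check. All work on plain data.frames / vectors.

# pairwise interval overlap on 1-based closed coordinates
ora_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 <= e2 & s2 <= e1
}

# O(n*m) blacklist filter
ora_filter_blacklisted <- function(peaks, bl) {
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    !any(ora_overlaps(peaks$chrom[i], peaks$start[i], peaks$end[i],
                      bl$chrom, bl$start, bl$end))
  }, logical(1))
  peaks[keep, , drop = FALSE]
}

# transitive-closure merge via union-find over all pairs
ora_merge <- function(df, max_gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  for (i in seq_len(n)) {
    js <- which(df$chrom == df$chrom[i] &
                  df$start <= df$end[i] + max_gap + 1 &
                  df$start[i] <= df$end + max_gap + 1)
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]))
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# edge-to-edge distance between 1-based closed intervals; NA across chroms
ora_distance <- function(c1, s1, e1, c2, s2, e2) {
  ifelse(c1 != c2, NA_real_,
         ifelse(s1 <= e2 & s2 <= e1, 0, pmax(s2 - e1, s1 - e2) - 1))
}

# all-pairs closest-SE links with ties, distance <= window
ora_closest <- function(genes, ses, window) {
  gi <- si <- integer(0); dd <- numeric(0)
  for (i in seq_len(nrow(genes))) {
    d <- ora_distance(genes$chrom[i], genes$start[i], genes$end[i],
                      ses$chrom, ses$start, ses$end)
    d[is.na(d)] <- Inf
    if (min(d) <= window) {
      js <- which(d == min(d))
      gi <- c(gi, rep(i, length(js))); si <- c(si, js); dd <- c(dd, d[js])
    }
  }
  data.frame(gene_index = gi, se_index = si, distance = dd)
}

# GSEA enrichment score by explicit prefix-sum walk
ora_es <- function(genes, scores, set, weight) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  w <- abs(scores[hit])^weight
  run <- numeric(N); cur <- 0; k <- 0
  for (i in seq_len(N)) {
    if (hit[i]) { k <- k + 1; cur <- cur + w[k] / sum(w) }
    else cur <- cur - 1 / (N - nh)
    run[i] <- cur
  }
  best <- 1
  for (i in seq_len(N)) if (abs(run[i]) > abs(run[best])) best <- i
  list(es = run[best], running = run, peak_index = best)
}

# independent rank computation with average ties (no rank())
ora_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Kruskal-Wallis H (tie-corrected) + Dunn pairwise z from first principles
ora_kw_dunn <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(values)
  r <- ora_ranks(values)
  h <- 0
  for (k in seq_along(groups)) {
    rk <- r[g == k]
    h <- h + length(rk) * (mean(rk) - (N + 1) / 2)^2
  }
  h <- h * 12 / (N * (N + 1))
  tie <- table(values)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  h <- h / corr
  kw_p <- stats::pchisq(h, length(groups) - 1, lower.tail = FALSE)
  sigma2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z[k] <- (mean(r[g == i]) - mean(r[g == j])) /
      sqrt(sigma2 * (1 / sum(g == i) + 1 / sum(g == j)))
  }
  list(h = h, kw_p = kw_p, z = z)
}

# random GRanges over a small genome
rand_granges <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                         max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(start, width = width))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
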
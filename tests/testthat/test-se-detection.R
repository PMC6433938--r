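test_that("promoter exclusion removes peaks in the TSS window per strand", {
  # + strand gene, TSS at 0-based 1000: window [−1000, 3000) clipped
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000),
                                 strand = "+")
  pk_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(901, 1100))
  pk_out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100))
  expect_equal(length(exclude_promoters(pk_in, gene, 2000)), 0L)
  expect_equal(length(exclude_promoters(pk_out, gene, 2000)), 1L)
  # − strand gene: window centred on the gene end
  gene_m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
                                   strand = "-")
  pk_tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(21000, 21500))
  pk_far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(23000, 23500))
  expect_equal(length(exclude_promoters(pk_tss, gene_m, 2000)), 0L)
  expect_equal(length(exclude_promoters(pk_far, gene_m, 2000)), 1L)
})

test_that("promoter exclusion matches a brute-force TSS-window oracle", {
  set.seed(11)
  for (rep in 1:5) {
    pk <- rand_granges(30, max_pos = 50000, max_width = 400)
    genes <- rand_granges(5, max_pos = 50000, max_width = 3000)
    BiocGenerics::strand(genes) <- sample(c("+", "-"), 5, replace = TRUE)
    flank <- 2000
    gdf <- gr_to_df(genes)
    gdf$strand <- as.character(BiocGenerics::strand(genes))
    tss <- ifelse(gdf$strand == "-", gdf$end, gdf$start)
    win_lo <- pmax(1, ifelse(gdf$strand == "-", tss - flank + 1, tss - flank))
    win_hi <- ifelse(gdf$strand == "-", tss + flank, tss + flank - 1)
    pdf <- gr_to_df(pk)
    keep <- vapply(seq_len(nrow(pdf)), function(i) {
      !any(pdf$chrom[i] == gdf$chrom & pdf$start[i] <= win_hi &
             win_lo <= pdf$end[i])
    }, logical(1))
    got <- gr_to_df(exclude_promoters(pk, genes, flank))
    want <- pdf[keep, , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("stitching joins peaks across gaps up to the stitch distance", {
  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 600))
  st1 <- stitch(single, 12500)
  expect_equal(length(st1), 1L)
  expect_equal(BiocGenerics::start(st1), 100L)
  expect_equal(st1$n_constituents, 1L)

  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 12501), c(500, 13000)))
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 13502), c(500, 14000)))
  expect_equal(length(stitch(near, 12500)), 1L)  # gap 12,000 bp
  expect_equal(length(stitch(far, 12500)), 2L)   # gap 13,001 bp
  expect_equal(length(stitch(GenomicRanges::GRanges(), 12500)), 0L)
})

test_that("stitching at distance zero returns the merged peaks themselves", {
  set.seed(21)
  pk <- rand_granges(60, max_pos = 10000, max_width = 300)
  st <- stitch(pk, 0)
  expect_equal(gr_to_df(st),
               gr_to_df(GenomicRanges::reduce(pk, ignore.strand = TRUE)))
})

test_that("coverage density implements rpm/bp with missing bases as zero", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  expect_equal(coverage_density(region, GenomicRanges::GRanges(), 1e6), 0)
  cov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  cov$score <- 10
  expect_equal(coverage_density(region, cov, 1e6), 10)
  expect_equal(coverage_density(region, cov, 2e6), 5)
  # half-covered region averages over its full width
  cov2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500))
  cov2$score <- 10
  expect_equal(coverage_density(region, cov2, 1e6), 5)
})

test_that("tangent cutoff recovers the analytic point of a quadratic curve", {
  x <- seq(0, 1, length.out = 1000)
  tc <- tangent_cutoff(x^2)
  expect_lt(abs(tc$cutoff - 0.25), 0.02)
})

test_that("tangent cutoff separates a two-regime step curve exactly", {
  d <- c(rep(1, 90), rep(100, 10))
  tc <- tangent_cutoff(d)
  expect_equal(sum(tc$is_se), 10L)
  expect_true(all(which(tc$is_se) > 90))
})

test_that("degenerate density curves yield no super-enhancers", {
  expect_true(all(!tangent_cutoff(rep(5, 50))$is_se))
  expect_true(all(!tangent_cutoff(c(1, 2))$is_se))
})

test_that("the SE/TE partition is scale-invariant and an upper set of the ranking", {
  set.seed(31)
  for (rep in 1:5) {
    d <- c(stats::rexp(150, 1), stats::rexp(15, 1 / 50))
    tc <- tangent_cutoff(d)
    tc_scaled <- tangent_cutoff(d * 7.3)
    expect_equal(tc$is_se, tc_scaled$is_se)
    if (any(tc$is_se) && any(!tc$is_se))
      expect_gt(min(d[tc$is_se]), max(d[!tc$is_se]))
  }
})

test_that("a planted dense cluster is called SE among isolated low peaks", {
  set.seed(41)
  # 10-peak dense cluster + 200 isolated low peaks on a 10 Mb chromosome
  cl_starts <- 50001 + (0:9) * 1500
  bg_starts <- 200000 + (0:199) * 14000
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(cl_starts, bg_starts), width = 500))
  cov <- pk
  cov$score <- c(rep(30, 10), rep(1, 200))
  genome <- se_genome(c(chr1 = 1e7))
  part <- call_superenhancers(pk, cov, GenomicRanges::GRanges(),
                              GenomicRanges::GRanges(), genome)
  expect_equal(length(part$se), 1L)
  expect_equal(BiocGenerics::start(part$se), 50001L)
  expect_equal(part$se$n_constituents, 10L)
  expect_equal(length(part$te), 200L)

  empty <- call_superenhancers(GenomicRanges::GRanges(), cov,
                               GenomicRanges::GRanges(),
                               GenomicRanges::GRanges(), genome)
  expect_equal(length(empty$stitched), 0L)
  expect_equal(length(empty$se), 0L)
})

test_that("net density is floored at zero when background exceeds signal", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 14001, 28001), width = 500))
  sig <- pk; sig$score <- c(0.1, 5, 10)
  bg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6)); bg$score <- 1
  part <- call_superenhancers(pk, sig, bg, GenomicRanges::GRanges(),
                              se_genome(c(chr1 = 1e6)))
  expect_true(all(part$stitched$net_density >= 0))
  expect_true(all(part$stitched$net_density <= part$stitched$signal_rpm_bp))
  expect_equal(part$stitched$net_density[1], 0)
})
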
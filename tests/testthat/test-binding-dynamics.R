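test_that("site labelling implements the persistent/primary/secondary definitions", {
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
  lab <- label_sites(b, a)
  expect_equal(as.character(lab$before$label), "PERSISTENT")
  expect_equal(as.character(lab$after$label), "PERSISTENT")
  expect_equal(as.integer(lab$before$partners[[1]]), 1L)

  lab2 <- label_sites(b, GenomicRanges::GRanges())
  expect_equal(as.character(lab2$before$label), "PRIMARY")
  lab3 <- label_sites(GenomicRanges::GRanges(), a)
  expect_equal(as.character(lab3$after$label), "SECONDARY")
})

test_that("labels match the all-pairs overlap oracle and satisfy the partition identity", {
  set.seed(51)
  for (rep in 1:5) {
    b <- rand_granges(40, max_pos = 20000, max_width = 400)
    a <- rand_granges(40, max_pos = 20000, max_width = 400)
    lab <- label_sites(b, a)
    bdf <- gr_to_df(b); adf <- gr_to_df(a)
    want_b <- vapply(seq_len(nrow(bdf)), function(i) {
      if (any(ora_overlaps(bdf$chrom[i], bdf$start[i], bdf$end[i],
                           adf$chrom, adf$start, adf$end))) "PERSISTENT" else "PRIMARY"
    }, character(1))
    want_a <- vapply(seq_len(nrow(adf)), function(i) {
      if (any(ora_overlaps(adf$chrom[i], adf$start[i], adf$end[i],
                           bdf$chrom, bdf$start, bdf$end))) "PERSISTENT" else "SECONDARY"
    }, character(1))
    expect_equal(as.character(lab$before$label), want_b)
    expect_equal(as.character(lab$after$label), want_a)
    # partition identities
    expect_equal(sum(lab$before$label == "PRIMARY") +
                   sum(lab$before$label == "PERSISTENT"), length(b))
    expect_equal(sum(lab$after$label == "SECONDARY") +
                   sum(lab$after$label == "PERSISTENT"), length(a))
    # symmetry: swapping conditions swaps PRIMARY and SECONDARY
    swapped <- label_sites(a, b)
    expect_equal(as.character(swapped$before$label) == "PERSISTENT",
                 as.character(lab$after$label) == "PERSISTENT")
    expect_equal(sum(swapped$before$label == "PRIMARY"),
                 sum(lab$after$label == "SECONDARY"))
  }
})

test_that("SE pattern classification follows the overlap-count rules", {
  ses <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 10001, 20001, 30001), width = 5000))
  mk <- function(starts, label) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 100))
    g$label <- factor(label, levels = c("PRIMARY", "PERSISTENT", "SECONDARY"))
    g
  }
  labeled_after <- c(
    mk(c(100, 600, 1100), "PERSISTENT"),          # SE 1: persistent only -> SE1
    mk(c(10100, 10600), "PERSISTENT"),            # SE 2: both -> SE2
    mk(c(11100, 11600, 12100, 12600, 13100), "SECONDARY"),
    mk(c(20100, 20600), "SECONDARY"))             # SE 3: secondary only -> SE3
  cl <- classify_se(ses, labeled_after, "after")
  expect_equal(as.character(cl$pattern), c("SE1", "SE2", "SE3", "UNBOUND"))
  expect_equal(cl$n_persistent, c(3L, 2L, 0L, 0L))
  expect_equal(cl$n_secondary, c(0L, 5L, 2L, 0L))

  labeled_before <- c(mk(c(100), "PERSISTENT"),
                      mk(c(10100), "PERSISTENT"), mk(c(11100), "PRIMARY"),
                      mk(c(20100, 20600), "PRIMARY"))
  clb <- classify_se(ses, labeled_before, "before")
  expect_equal(as.character(clb$pattern), c("SE4", "SE5", "SE6", "UNBOUND"))
  # no SE overlapping a labelled site is UNBOUND
  expect_true(all((clb$n_persistent + clb$n_primary + clb$n_secondary == 0) ==
                    (clb$pattern == "UNBOUND")))
})

test_that("transition fates distinguish persistence, reclassification and loss", {
  before <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 20001, 40001), width = 5000))
  before$pattern <- factor(c("SE4", "SE4", "SE6"), levels = se_pattern_levels())
  after <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 20001), width = 5000))
  after$pattern <- factor(c("SE1", "SE2"), levels = se_pattern_levels())
  tr <- transitions(before, after)
  expect_equal(tr$fate, c("persists_as", "reclassified_as", "lost"))
  expect_equal(tr$after_pattern, c("SE1", "SE2", NA))
  expect_false(any(tr$multi_mapping))
  # a before-SE spanning two after-SEs is recorded twice and flagged
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 30000))
  wide$pattern <- factor("SE5", levels = se_pattern_levels())
  tr2 <- transitions(wide, after)
  expect_equal(nrow(tr2), 2L)
  expect_true(all(tr2$multi_mapping))
  expect_equal(tr2$fate, c("persists_as", "persists_as"))  # SE5 -> SE1 or SE2
})

test_that("pattern census counts every pattern and ignores input order", {
  expect_equal(sum(pattern_census(character(0))), 0L)
  pats <- c(rep("SE1", 5), rep("SE2", 7), rep("SE3", 3))
  cen <- pattern_census(pats)
  expect_equal(unname(cen[c("SE1", "SE2", "SE3")]), c(5L, 7L, 3L))
  expect_equal(sum(cen), length(pats))
  set.seed(61)
  expect_equal(pattern_census(sample(pats)), cen)
})
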
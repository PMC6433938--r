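test_that("configuration invariants are enforced", {
  expect_error(sim_config(intra_cluster_gap = 13000), "stitch_distance")
  expect_error(sim_config(inter_cluster_gap = 50000), "100 kb")
  expect_error(sim_config(snp_enrichment_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulate_bundle(sim_config(chrom_length = 1.5e6),
                               withr::local_tempdir()), "infeasible")
})

test_that("the truth table lists exactly the planted entities", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 3)
  b <- simulate_bundle(cfg, dir)
  cl <- b$truth$clusters
  expect_equal(sum(cl$archetype == "persistent_only"), 1L)
  expect_equal(sum(cl$archetype == "persistent_secondary"), 2L)
  expect_equal(sum(cl$archetype == "secondary_only"), 1L)
  expect_equal(nrow(cl), 6L)
  expect_equal(sum(cl$pattern_after == "SE2"), 2L)
  expect_equal(sum(cl$pattern_before == "SE4"), 3L)  # persistent-only + persistent+secondary
  expect_equal(nrow(b$truth$genes), cfg$n_genes)
  expect_equal(nrow(b$truth$snps), cfg$n_snps)
  expect_false(any(duplicated(b$truth$clusters$id)))
  expect_false(any(duplicated(b$truth$peaks$name)))
})

test_that("the same seed reproduces the bundle byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(tiny_config(seed = 11), d1)
  b2 <- simulate_bundle(tiny_config(seed = 11), d2)
  for (nm in names(b1$files)) {
    expect_equal(unname(tools::md5sum(b1$files[[nm]])),
                 unname(tools::md5sum(b2$files[[nm]])), info = nm)
  }
  b3 <- simulate_bundle(tiny_config(seed = 12), withr::local_tempdir())
  expect_false(tools::md5sum(b1$files$peaks_after) ==
                 tools::md5sum(b3$files$peaks_after))
})

test_that("generated files round-trip losslessly through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 5)
  b <- simulate_bundle(cfg, dir)
  tp <- b$truth$peaks
  before_truth <- tp[tp$presence %in% c("both", "before_only"), ]
  pk <- read_bed(b$files$peaks_before, "narrowPeak")
  expect_equal(BiocGenerics::start(pk), before_truth$start)
  expect_equal(BiocGenerics::end(pk), before_truth$end)
  expect_equal(pk$name, before_truth$name)
  genes <- read_genes(b$files$genes, "tsv")
  expect_equal(BiocGenerics::start(genes), b$truth$genes$start)
  expect_equal(genes$name, b$truth$genes$name)
  snps <- read_bed(b$files$snps, "bed3")
  expect_equal(BiocGenerics::start(snps), b$truth$snps$pos)
  cs <- read_chrom_sizes(b$files$chrom_sizes)
  expect_equal(unname(cs), rep(cfg$chrom_length, cfg$n_chroms))
  fa <- Biostrings::readDNAStringSet(b$files$genome_fasta)
  expect_equal(unname(Biostrings::width(fa)), rep(cfg$chrom_length, cfg$n_chroms))
})

test_that("stitching at the configured distance reconstructs the planted clusters", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 9)
  b <- simulate_bundle(cfg, dir)
  pk <- read_bed(b$files$peaks_after, "narrowPeak")
  st <- stitch(pk, cfg$stitch_distance)
  cl <- b$truth$clusters
  cl_after <- cl[cl$pattern_after != "ABSENT", ]
  # every planted after-condition cluster appears as one stitched region
  # (persistent+secondary clusters span their full planted extent after)
  full <- cl_after[cl_after$archetype %in% c("persistent_only", "secondary_only",
                                             "persistent_secondary"), ]
  stdf <- gr_to_df(st)
  for (i in seq_len(nrow(full))) {
    hit <- stdf$chrom == full$chrom[i] & stdf$start == full$start[i] &
      stdf$end == full$end[i]
    expect_equal(sum(hit), 1L)
  }
  # isolated background peaks stay singletons
  expect_equal(sum(st$n_constituents == 1),
               length(st) - nrow(cl_after))
})

test_that("unplanted SNPs land inside SEs at about the SE genome fraction", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 13, snp_enrichment_rate = 0, n_snps = 300)
  b <- simulate_bundle(cfg, dir)
  cl <- b$truth$clusters
  se_bp <- sum(cl$end[cl$pattern_after != "ABSENT"] -
                 cl$start[cl$pattern_after != "ABSENT"] + 1)
  frac <- se_bp / (cfg$n_chroms * cfg$chrom_length)
  inside <- sum(b$truth$snps$inside)
  expect_lt(abs(inside - cfg$n_snps * frac),
            4 * sqrt(cfg$n_snps * frac * (1 - frac)) + 1)
})

test_that("recovery verification reports perfect scores on clean outputs and zero rates gracefully", {
  run <- default_run()
  rec <- verify_recovery(run$bundle$truth, run$class_before, run$class_after,
                         labels = run$labels)
  expect_equal(rec$se_recovered_after, 1)
  expect_equal(rec$pattern_accuracy_after, 1)
  # empty outputs: zero recovery, no crash
  empty <- classify_se(GenomicRanges::GRanges(), run$labels$after, "after")
  rec0 <- verify_recovery(run$bundle$truth, empty, empty)
  expect_equal(rec0$se_recovered_after, 0)
})
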
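# Shared fixtures. The default-scale simulation and pipeline run are
# computed once per test session and reused across test files.

# reduced-geometry configuration for fast structural tests
tiny_config <- function(seed = 7, ...) {
  defaults <- list(seed = seed, chrom_length = 2e6,
                   n_persistent_only = 1, n_persistent_secondary = 2,
                   n_secondary_only = 1, n_persistent_primary = 1,
                   n_primary_only = 1,
                   inter_cluster_gap = 115000, n_background_peaks = 30,
                   n_genes = 20, n_snps = 20)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

# default-conditions end-to-end run, cached for the session
default_run <- function() {
  if (is.null(.fixture_env$run)) {
    dir <- file.path(tempdir(), "sedyn_default_run")
    cfg <- sim_config(seed = 42)
    bundle <- simulate_bundle(cfg, file.path(dir, "inputs"))
    genome <- se_genome(read_chrom_sizes(bundle$files$chrom_sizes),
                        read_bed(bundle$files$blacklist, "bed3"))
    genes <- read_genes(bundle$files$genes, "tsv")
    pk_b <- read_bed(bundle$files$peaks_before, "narrowPeak")
    pk_a <- read_bed(bundle$files$peaks_after, "narrowPeak")
    sig_b <- read_bedgraph(bundle$files$signal_before)
    sig_a <- read_bedgraph(bundle$files$signal_after)
    bg <- read_bedgraph(bundle$files$background)
    tm <- bundle$truth$total_mapped_reads
    part_b <- call_superenhancers(pk_b, sig_b, bg, genes, genome,
                                  total_reads_signal = tm,
                                  total_reads_background = tm)
    part_a <- call_superenhancers(pk_a, sig_a, bg, genes, genome,
                                  total_reads_signal = tm,
                                  total_reads_background = tm)
    labels <- label_sites(pk_b, pk_a)
    class_b <- classify_se(part_b$se, labels$before, "before")
    class_a <- classify_se(part_a$se, labels$after, "after")
    .fixture_env$run <- list(cfg = cfg, bundle = bundle, genome = genome,
                             genes = genes, part_before = part_b,
                             part_after = part_a, labels = labels,
                             class_before = class_b, class_after = class_a)
  }
  .fixture_env$run
}
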
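Package: SEdynamics
Title: Signal-Inducible Super-Enhancer Calling, Dynamics Classification and
    Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls super-enhancers from transcription-factor ChIP-seq peak
    sets by ROSE-style stitching and a slope-1 tangent cutoff on the ranked
    signal-density curve, classifies binding sites across a
    vehicle-to-stimulated contrast into primary, persistent and secondary
    sites and the derived SE1-SE6 super-enhancer patterns, links
    super-enhancers to nearby genes, tests enrichment of disease-risk SNPs in
    region sets by width-preserving genome permutation, and provides
    expression-side statistics (CPM filtering, simple differential
    expression, Kruskal-Wallis with Dunn post-hoc tests, GC content) and a
    pre-ranked gene-set enrichment statistic. A synthetic-data generator
    plants super-enhancer patterns, SNP enrichment and expression effects
    with a machine-readable truth table so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
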
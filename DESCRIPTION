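Package: clipfoot
Title: CLIP-Seq Footprint Construction, Reproducibility, and Splicing
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of protein-RNA crosslinking
    immunoprecipitation (CLIP-seq) experiments at the peak level:
    background depletion and merging of binding sites into footprints,
    majority-consensus footprints across biological replicates,
    reproducibility assessment with the Gaussian copula mixture model of
    the irreproducible discovery rate (IDR) including ENCODE-style rescue
    and self-consistency ratios from peak-level pseudo-replicates,
    condition-level comparison of binding profiles (bound-gene set
    partitions, gained and lost footprints, k-mer motif enrichment
    against a dinucleotide-preserving shuffle null), and quantification
    of companion splicing and expression assays (percent spliced-in,
    three-primer inclusion ratios, restriction-digest isoform fractions,
    delta-delta-Ct fold changes, neurite summaries, and exact
    small-sample Mann-Whitney tests).  A synthetic-data module generates
    every input the pipeline consumes, with the statistical structure
    the analysis assumes, so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
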
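Package: ampliClone
Title: Clone Discrimination and Amplicon Marker Panels for Vegetatively
    Propagated Cultivars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers clone-specific somatic variants among vegetatively
    propagated plant lineages (grapevine clonal selections in particular)
    from multi-sample variant calls, and turns them into amplicon-sequencing
    identification panels. Provides replicate-concordance and exclusivity
    filtering of genotype matrices, variant normalisation and quality
    filtering, summary statistics (Ts/Tv, heterozygous fraction, per-window
    densities), PCA of clones, amplicon marker selection under length
    constraints, allele counting and genotype calling from amplicon reads,
    and a clone identification procedure in which a single positive
    heterozygous marker suffices. A seeded synthetic clonal-cohort generator
    (diploid reference, shared background heterozygous variants, planted
    clone-exclusive SNVs and InDels, per-replicate call noise, amplicon
    reads) supports testing the whole pipeline against a known truth table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
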
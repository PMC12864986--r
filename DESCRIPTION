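Package: epromoterscan
Title: Identification of Epromoter-Regulated Clusters of Stress-Induced Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies clusters of co-induced stress-response genes from
    processed expression and transcription-factor ChIP-seq data, and classifies
    which clusters are regulated by an Epromoter (a promoter that recruits the
    key stress transcription factor on behalf of its unbound neighbours).
    Provides TSS-proximity and TAD-based gene clustering, promoter-window
    peak assignment including alternative TSSs, nearest-TSS distance
    distribution statistics (Kolmogorov-Smirnov comparison against seeded
    random gene nulls and a signed Q-Q deviation score), motif-density
    binning over promoter categories, proximal versus distal peak profiling
    around clusters, and a synthetic-fixture generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
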
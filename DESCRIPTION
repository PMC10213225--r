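Package: famscan
Title: Gene Family Characterization: Duplication Modes, Ka/Ks, Promoters and
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested pipeline for characterizing a plant
    gene family from a genome assembly and annotation: member renaming by
    chromosomal order, protein physicochemical properties (molecular weight,
    theoretical pI, GRAVY, instability and aliphatic indices), promoter
    cis-acting element and SSR scanning, collinear-block detection from
    homology hits, duplication-mode classification (singleton, dispersed,
    proximal, tandem, WGD/segmental) with Ks-based whole-genome-duplication
    assignment, Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction, and expression summarization (TPM, log2(TPM+1), row scaling,
    2^-ddCT fold changes). A synthetic-genome generator plants duplication
    events of known age and type so every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
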
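Package: trioDNV
Title: Trio-Based De Novo Variant Filtering, Mutation-Rate Estimation, and
    CRISPR Off-Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting germline de novo variants in family trios
    from two-caller whole-genome variant call sets. Implements a multi-stage
    filter cascade (caller intersection, cohort uniqueness, known-variant
    database, parental depth and allelic balance, phred-scaled genotype
    likelihood patterns, soft-clip fraction, and context review flags),
    estimation of the per-base-pair per-generation mutation rate from a
    coverage-window effective genome size, nine-class substitution spectrum
    summaries, PAM-aware mismatch-tolerant CRISPR off-target site search
    with a distance-to-site null model and Kolmogorov-Smirnov comparison,
    and kinship-based pedigree validation. A synthetic-trio simulator with
    full ground truth provides a self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
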
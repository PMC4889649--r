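Package: laikit
Title: Post-Processing Toolkit for Local Ancestry Calls in Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with per-haplotype local ancestry calls in
    admixed cohorts: ancestry-specific principal components via
    multidimensional scaling of masked haplotypes with missing-data-aware
    distances, Mendelian-inconsistency evaluation of ancestry calls for
    parent-offspring pairs and trios on autosomes and chromosome X,
    X-chromosome male coding schemes (pseudodiploid reference pairing and
    homozygous-diploid coding), call-set concordance with maximal-agreement
    diploid matching, posterior-probability summaries, and a synthetic
    admixed-genome simulator with known ancestry tracts for validating
    every stage without access to controlled human data. Reads phased VCF,
    RFMix-style Viterbi and posterior text, pedigree and site-map tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
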
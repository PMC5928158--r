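Package: trisomap
Title: Integrated Quantitative Transcriptome Maps for Trisomic vs. Euploid
    Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds integrated quantitative transcriptome maps from
    heterogeneous microarray expression tables, for comparing an aneuploid
    (e.g. trisomy 21) sample pool against a euploid one. Implements
    per-sample global normalization with non-positive thresholding, scaled
    quantile normalization across platforms with different feature counts,
    per-locus consensus expression values, differential A/B ratio maps with
    gene-dosage band classification, sliding-window chromosomal segment
    calling by hypergeometric tests with false discovery rate control, a
    25 kb single-gene mode, per-chromosome dosage summaries, and the
    2^-ddCt qPCR validation arithmetic. Ships a ground-truthed synthetic
    multi-platform data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
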
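Package: dismir
Title: Read-Level Cancer Detection from Plasma cfDNA Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tumor-derived reads in plasma cell-free DNA
    whole-genome bisulfite sequencing data. Identifies cancer-specific
    differentially methylated regions as "switching regions" from
    per-read methylation ratios, scores individual reads with a joint
    sequence-plus-methylation deep model (convolution, max-pooling,
    bidirectional LSTM, convolution and dense layers) trained in-package,
    estimates the tumor-derived read fraction by maximum-posterior grid
    search, and provides model-interpretation tools (kernel position
    frequency matrices with a methylation letter, MEME export,
    CpG-demethylation perturbation scores, rank-based effect sizes,
    Fisher's combined probability test). A bisulfite-read simulator
    generates fully synthetic cohorts so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
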
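Package: delaycor
Title: Time-Delayed Spearman Co-Expression Analysis of mRNA and Protein
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects simultaneous and time-delayed co-expression between
    gene expression profiles measured over ordered conditions (e.g. life
    cycle stages) or unordered sample panels.  The co-expression score is
    the Spearman rank correlation of truncated, time-shifted profile
    pairs; significance is assessed by a Monte-Carlo permutation test on
    the maximum score over shifts with a per-pair Bonferroni correction.
    Includes readers and writers for expression matrices, a synthetic
    paired mRNA/protein data generator with planted lags for validation,
    class-count and co-expression transfer summaries with chi-square
    contrasts, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
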
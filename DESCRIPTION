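Package: pufcode
Title: Deriving and Applying a PUF-Domain RNA Recognition Code from
    Selection Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deep mutational scanning of Pumilio/PUF-domain
    tripartite recognition motifs (TRMs) selected by yeast three-hybrid
    against base-varied RNA targets. Provides a synthetic-data generator
    for NNK TRM libraries and growth selection, FASTQ read decoding and
    variant counting, log2 enrichment (interaction) and specificity
    scoring, hit selection, clustering and sequence-logo construction,
    derivation of a per-repeat per-base recognition-code table, design of
    PUF domains against arbitrary 8-mer RNA targets, probabilistic RNA
    oligo array generation with register-shift diagnostics, and fitting
    of equilibrium dissociation constants from binding titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
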
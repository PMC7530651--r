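Package: txrank
Title: Expression Ranking of Transcript Isoforms Across Tissues
Version: 0.1.0
Authors@R: person("txrank", "maintainers", email = "txrank@example.org",
    role = c("aut", "cre"))
Description: Ranks the transcript isoforms of each gene by expression level
    across a panel of tissues, with a deterministic CDS-length and
    transcript-length tie-break cascade.  Computes per-tissue rank tables,
    dominant-isoform expression fractions, coefficient-of-variation scores,
    and detects rank1 switch events (genes whose per-tissue dominant isoform
    differs from the overall top-ranked one).  Reads GTEx-style GCT 1.2
    transcript TPM matrices and GENCODE-style annotation, cross-tabulates
    computed ranks against MANE-select transcripts, and ships a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
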
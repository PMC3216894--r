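Package: chromtrans
Title: Chromatin State Transitions from Promoter Tiling ChIP-chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for H3K4me3/H3K27me3 promoter tiling-array
    (ChIP-chip) data from paired normal and tumor samples: quantile
    normalization and replicate merging of probe intensities, sliding-window
    Z-score computation, rule-based enriched-region calling, bivalent-domain
    detection, classification of normal-to-tumor chromatin-state transitions
    over the {unmarked, H3K4me3, H3K27me3, bivalent} alphabet, strand-aware
    promoter annotation, and downstream enrichment and paired-expression
    statistics. Includes a synthetic-data generator that plants per-promoter
    chromatin states so the full pipeline is testable without any array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
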
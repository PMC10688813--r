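Package: mockqc
Title: Quality Control of Mock-Community Positive Controls in 16S rRNA
    Amplicon Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assesses mock-community (positive-control) samples from 16S
    rRNA gene amplicon sequencing runs. Amplicon sequence variants (ASVs)
    are classified against the mock's expected reference sequences with a
    k-mer word-presence naive-Bayes classifier and bootstrap confidence,
    aggregated to species level, and compared to the mock's theoretical
    composition via Spearman rank correlation. Per-sample diagnostics
    include the correlation table, the percentage of unclassifiable
    ("Unknown") reads, and per-taxon bias panels. A synthetic-data module
    generates reference panels, theoretical compositions and ASV tables,
    including a contamination dilution series, so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
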
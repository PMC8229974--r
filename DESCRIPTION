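Package: amplimeth
Title: Promoter CpG-Island Methylation Analysis from Bisulfite Amplicon
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies promoter CpG-island methylation of the TRAIL death
    receptor genes DR4 (TNFRSF10A) and DR5 (TNFRSF10B) from bisulfite
    amplicon sequencing reads, and relates it to gene expression,
    cell-surface receptor levels and TRAIL sensitivity in leukemia cell
    panels. Provides in-silico bisulfite PCR from primer pairs,
    bisulfite-aware global read alignment with per-read conversion-
    efficiency QC, per-CpG and mean percent methylation summaries,
    methylation and TRAIL-sensitivity classification schemes,
    rank-based association statistics, aggregation of 450k-style
    methylation-array cohorts over TSS200 CpG-island probes, and
    simulators for reads, cell-line panels and array cohorts so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
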
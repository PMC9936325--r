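Package: sdrnaswitch
Title: Small RNA Profiling of the DICER-Dependent miRNA to DICER-Independent
    sdRNA Expression Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing two small RNA-seq
    libraries (e.g. wild-type versus DICER-knockout) against a combined
    miRNA + snoRNA precursor reference. Reads are placed by perfect,
    ungapped, full-read matching restricted to 16-32 nt; snoRNA coverage
    profiles are summarised into discrete snoRNA-derived RNA (sdRNA) loci
    anchored at read 5'-end peaks; features are quantified in reads per
    million with an expression floor; and each feature is classified as
    upregulated, downregulated or unchanged by percent-of-wild-type
    thresholds. A seeded simulator generates paired libraries with known
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
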
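Package: tcrioct
Title: Inter-Organ Clone Tracking for T Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bulk T cell receptor (TCR) repertoires of CD8+
    T cells sampled from multiple tissue compartments (tumor-draining
    lymph node, peripheral blood, tumor) of the same animal. Reads
    tab-delimited clonotype tables, removes non-functional clones,
    normalizes sequencing coverage by hypergeometric downsampling,
    computes repertoire-structure statistics (1-Pielou clonality,
    diversity above a frequency threshold, rank-quantile statistics, V/J
    segment usage), and performs Inter-Organ Clone Tracking: detection of
    clonotypes shared among compartments, their combined frequencies,
    major/minor overlap-pattern classification, public-clone analysis
    across animals, and tracking of named clones by their CDR3 sequence.
    Includes a synthetic multi-mouse, multi-compartment repertoire
    generator with planted shared, public and spike-in clones so the full
    pipeline can be exercised and validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
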
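Package: topdemux
Title: Identification of Co-Fragmented Proteoform Pairs from Multiplexed
    Top-Down Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies two co-fragmented proteoforms from heterogeneous
    multiplexed top-down DDA tandem mass spectra. Implements primary-precursor
    selection with error-prone spectrum detection and the normalized matched
    fragment mass (NNMFM) score, a two-round search-and-subtract database
    search over deconvoluted neutral fragment masses with zero or one unknown
    mass shift, target-decoy false discovery rate control at the spectrum and
    proteoform level, proteoform grouping, pseudo-multiplexed (SPMS/RPMS)
    benchmark construction, precursor-selection-error / random-matching-error
    evaluation, and a ground-truthed synthetic spectrum simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
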
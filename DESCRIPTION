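Package: targetec
Title: Instance-Based Error Correction of Short Reads Around a Target Gene
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Targeted ("instance-based") substitution-error correction for
    Illumina-style whole-genome sequencing reads. Reads relevant to a single
    gene of interest are extracted from a read set by identity-tolerant
    mapping against the flank-extended gene reference, stacked into a
    position-sorted alignment array, and corrected conservatively using
    column-dominance statistics (per-column base frequencies, one- to
    four-type dominance classes and per-base priorities). Includes SAM import
    of external alignments, a synthetic whole-genome read simulator with a
    planted-SNP individual genome and a complete truth log, and the standard
    precision/recall/gain evaluation of error correctors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
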
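Package: dupfate
Title: Expression Fate and Regulatory Divergence of Recent Gene Duplicates
Version: 0.1.0
Authors@R:
    person("dupfate", "developers", email = "dupfate@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize expression divergence between ancestral
    and derived copies of recently duplicated genes. Implements
    cross-tissue expression-conservation statistics against a single-copy
    outgroup ortholog and fate classification (conservation,
    pseudogenization, neofunctionalization, subfunctionalization
    candidates), copy-number-adjusted paralog differential expression,
    EM reallocation of multi-mapping reads across near-identical
    duplicated loci, permutation-based depletion tests of genomic
    features in duplicated regions, and position-weight-matrix scanning
    for paralog-specific gains and losses of transcription-factor
    binding sites. A synthetic-data module generates gene families,
    paralogous sequences with paralog-specific variants, multi-mapping
    read sets and peak landscapes with known ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
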
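Package: trfcat
Title: Classification and Profiling of tRNA 3'-End Maturation States and
    tRNA-Derived Fragments from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small RNA-seq reads mapping to a single-copy tRNA
    locus into maturation and fragmentation categories (precursor, immature,
    mature-CCA, CC-ended, 3'-tRFs, 5'/internal fragments, incorrectly tailed
    species) and profiles how these subpopulations change across timepoints
    and conditions. Provides locus/window construction from FASTA+BED, adapter
    trimming and read filtering, a local aligner with mapping filters,
    disambiguation of genomically encoded trailers from post-transcriptional
    tails, per-sample category profiles with replicate means and standard
    errors, and a seeded read simulator with ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    S4Vectors,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
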
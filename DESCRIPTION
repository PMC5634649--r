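Package: kdiffasm
Title: Approximate String Matching with k Differences over DNA Texts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Online approximate string matching under the Levenshtein
    (edit) distance with a k-differences threshold, for DNA and other
    small-alphabet texts.  Three interchangeable engines compute the
    semi-global dynamic-programming distance grid: the classic sequential
    recurrence (the reference oracle, in C), a dependency-eliminated
    row-parallel recurrence driven by a last-occurrence index in which
    every column of a row is independent of the others, and a dataflow
    simulator of the warp-shuffle formulation of that recurrence that
    models per-lane registers, register exchange between lanes,
    warp-boundary memory fallback, and per-run memory-traffic counters.
    Includes FASTA input, TSV/BED match reporting, a seeded synthetic DNA
    generator with planted approximate occurrences, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
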
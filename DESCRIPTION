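Package: rangetable
Title: A Tidy Grammar of Genomic Range Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A fluent, endomorphic algebra for tidy tables of genomic ranges:
    anchored range arithmetic (anchoring, width setting, shifting, stretching,
    flanking), parallel and merging interval set operations (reduce, disjoin,
    coverage, complement), overlap- and proximity-based relational joins with
    inner/intersect/left merge modes, grouping and aggregation verbs in the
    dplyr style, and exact readers/writers for BED, GFF3, bedGraph and
    chrom.sizes files. Includes seeded synthetic-range simulators and naive
    brute-force oracles for verification, and a command-line interface over
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    S4Vectors,
    IRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
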
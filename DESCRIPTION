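Package: stwinscan
Title: Detection and Evolutionary Analysis of Sister Spliceosomal Twin Introns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans fungal genomic DNA for canonical U2 introns and donor-disrupted
    (D1,2) spliceosomal twin introns (stwintrons) using a configurable degenerate
    motif grammar, simulates their two-step excision (including the splinter
    intermediate and the alternative one-step product with an exonised G1),
    collects and classifies sister (stw)intron families by global alignment,
    characterises terminal inverted repeats and the internal 10-nt palindrome by
    self-reverse-complement alignment, models the three stwintron-to-canonical-
    intron derivation paths (type-1 crop, microhomology-mediated type-2 crop,
    long intron), analyses insertion context (intron phase, tandem-site
    duplications, seamless integration, junction position-frequency matrices),
    and ships a synthetic-genome generator with machine-readable ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
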
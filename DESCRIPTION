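Package: squigglemap
Title: Signal-Space Mapping of Raw Nanopore Reads by Subsequence Dynamic
    Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps raw nanopore current traces ("squiggles") directly against
    a reference genome in signal space, without basecalling, for selective
    sequencing (Read Until) decisions.  A k-mer pore model converts a base
    reference into synthetic per-strand signal; raw reads are segmented into
    events, adapter-trimmed, and assembled into fixed-length queries; query
    and reference are matched by subsequence dynamic time warping (sDTW)
    under Manhattan distance.  Three interchangeable sDTW engines are
    provided: a full-matrix floating-point engine with backtracking, a
    linear-space end-position engine, and a bit-accurate 16-bit fixed-point
    wavefront engine that models an anti-diagonal processing-element chain,
    including its overflow behaviour.  Mapping quality is derived from best
    and second-best alignment scores and drives an accept/reject policy over
    BED target regions.  A seeded simulator generates pore models,
    references and raw reads with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
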
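Package: dnalz
Title: Lossless Reference-Free DNA Compression via Bitstream Transforms and LZ77
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lossless, reference-free codec for DNA sequences over the
    {A,C,G,T} alphabet. A six-step stage-1 transform converts a sequence into
    six printable-ASCII files (an indicator bitstream of the most frequent
    base with its zero-runs halved, a pair-merged residual stream recoded
    with a prefix-free code, and a metadata side channel), which are then
    compressed with a sliding-window LZ77 coder. The exact inverse pipeline
    restores the input byte-for-byte. Also implements the Nour-Sharawi
    phase-1 three-file splitter and its bit accounting for side-by-side
    comparison, a synthetic-sequence generator with controlled base
    composition and repeat content, and a single-file archive container with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
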
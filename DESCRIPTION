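Package: viralrefine
Title: Error Correction, Extension and Polishing of Viral Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Refines single viral contigs assembled from metagenomic short
    reads. Detects chimeric joins by non-uniform per-base depth of coverage
    and keeps the longest uniformly covered segment, detects circularity or
    terminal redundancy by self-alignment of a terminal window and trims the
    redundant copy, grows the contig by iterative edge-local greedy overlap
    assembly with a trim-and-retry fallback, and polishes the final sequence
    by pileup majority consensus. Ships a paired-end short-read simulator so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
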
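Package: dcscan
Title: Detection of RNase III-Cleaved Small Double-Stranded RNAs from
    p19-Captured Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for small RNA sequencing libraries of
    p19-captured ~21-22 bp double-stranded RNAs in bacteria. Calls
    dsRNA read clusters (sliding-window read-count threshold), detects
    in vivo RNase III cleavage signatures as opposite-strand read pairs
    forming perfect duplexes with 2-nt 3' overhangs, profiles positional
    nucleotide composition around modeled cleavage sites, counts sense
    and antisense reads per gene, and compares cluster sets against
    external genomic feature sets with length-matched random controls.
    Includes a fully seeded synthetic-data generator that emulates
    overlapping sense/antisense transcription, RNase III digestion and
    p19 capture so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
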
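Package: conskex
Title: Conservative Iterative De Bruijn Graph Assembly of Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conservative de novo assembler for Illumina-style short reads
    built on iterative De Bruijn graphs with strand-aware k-mer counting.
    Overrepresented 19-mers clip adapter-bearing reads; a k-mer spectrum
    drives automatic detection of count thresholds, the k-mer ladder and the
    insert size; contig extension applies count, strand-balance and bounded
    path-exploration filters with bidirectional verification so that
    ambiguity produces a contig break rather than a guess; paired reads are
    connected into fragments that supply k-mers longer than the mate length,
    resolving repeats shorter than the insert.  Includes simulators for
    substrings and contamination read sets and a seed-and-chain assembly
    evaluator (N50, mismatches per 100 kb, misassemblies, length deviation).
    Output is deterministic: canonical contig orientation, canonical circular
    rotations and alphabetical ordering make repeated runs byte-identical.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
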
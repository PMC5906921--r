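Package: genelog
Title: Partitioned Append-Only Message Logs for Streamed Genomic Sequence Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-backed, in-process implementation of partitioned,
    append-only, compactable message logs (topics) as a repository for
    genomic sequences, together with the streaming machinery built on top
    of them: producer partitioning by key hash, consumer groups with
    balanced partition assignment and offset commits, log compaction with
    tombstone deletion, simulated replica placement, FASTA chunking into
    bounded-size messages, autonomous loader and GC-content agents
    coordinated through instruction topics, completion detection via
    back-markers and output equilibrium, a topic-based reciprocal
    best-match average nucleotide identity (ANI) pipeline, and a
    scalability benchmark harness comparing the agent pipeline against a
    multithreaded single-process baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
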
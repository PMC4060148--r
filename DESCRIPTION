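Package: coocnet
Title: Account-Level Keyword Co-Occurrence Networks from Microblog Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds keyword co-occurrence networks from per-account
    collections of short messages (tweets). Tweets are split into lines at
    sentence-final periods, tokenized against a pluggable term dictionary,
    reduced to noun lemmas, and synonym-merged; an unordered word pair is
    then weighted by the number of distinct accounts in which it co-occurs
    on at least one line, the top-K heaviest pairs form an undirected
    network, and a from-scratch spring embedder (Hooke-law springs on edges,
    Coulomb repulsion between nodes) lays it out at force equilibrium.
    Includes a seeded synthetic corpus generator with planted topical
    co-occurrence structure, profile-based account selection, per-account
    tweet capping, GraphML and TSV export, and a keyword category report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    withr,
    xml2,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
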
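Package: scholarprofiler
Title: Scalable Scientific-Interest Profiling from PubMed Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds narrative research-interest profiles for biomedical
    researchers from their PubMed publication records and evaluates them
    against self-written profiles. Publications are filtered by authorship
    position and a recency window; profiles are generated either from MeSH
    keywords split into methodology and health domains or from abstracts via
    topic-grouped divide-and-conquer summarization over a pluggable
    text-generation backend (a deterministic extractive backend is packaged).
    Evaluation covers lexical overlap (BLEU, ROUGE-L, METEOR), vocabulary
    shift (KL divergence of TF-IDF distributions and a zero-TF-IDF novel-term
    count filtered through the MeSH vocabulary), greedy-matching embedding
    similarity (BERTScore), five syntactic measures over dependency parses,
    LDA topic-stability diversity scores, and Gwet's AC1 inter-rater
    agreement. A seeded synthetic-corpus generator with planted structure
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
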
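# hand-built parse fixtures and small record builders used across tests

chain_sentence <- function(n) {
  parsed_sentence(form = paste0("w", seq_len(n)),
                  upos = rep("NOUN", n),
                  head = c(1L, seq_len(n - 1L))[seq_len(n)],
                  deprel = c("root", rep("dep", n - 1L)))
}

star_sentence <- function(n) {
  parsed_sentence(form = paste0("w", seq_len(n)),
                  upos = rep("NOUN", n),
                  head = rep(1L, n),
                  deprel = c("root", rep("dep", n - 1L)))
}

# "saw man with telescope": verb root, object noun, 2-token adpositional
# phrase (with + telescope) attached low - 2 earlier attachment sites
vnpn_sentence <- function() {
  parsed_sentence(
    form = c("saw", "man", "with", "telescope"),
    upos = c("VERB", "NOUN", "ADP", "NOUN"),
    head = c(1L, 1L, 4L, 2L),
    deprel = c("root", "obj", "case", "nmod")
  )
}

toy_record <- function(pmid, year = 2020L, surnames = c("Rivera", "Chen"),
                       givens = NULL, abstract = "some abstract text",
                       mesh = character()) {
  n <- length(surnames)
  if (is.null(givens)) givens <- rep("Dana", n)
  publication_record(
    pmid = as.character(pmid), title = paste("Title", pmid),
    abstract = abstract,
    authors = tibble::tibble(surname = surnames, given = givens,
                             affiliation = NA_character_),
    mesh_headings = tibble::tibble(descriptor = mesh,
                                   major = rep(FALSE, length(mesh))),
    pub_year = year
  )
}

fixture_mesh_vocab <- function() {
  load_mesh_vocabulary(system.file("extdata", "example_mesh_desc.xml",
                                   package = "scholarprofiler"))
}

# small planted two-topic corpus for recovery tests
planted_corpus <- function(n_per_topic = 5L, len = 40L, seed = 1L,
                           overlap_words = character()) {
  set.seed(seed)
  voc1 <- c(paste0("alpha", 1:25), overlap_words)
  voc2 <- c(paste0("beta", 1:25), overlap_words)
  docs <- c(
    lapply(seq_len(n_per_topic), function(i) sample(voc1, len, replace = TRUE)),
    lapply(seq_len(n_per_topic), function(i) sample(voc2, len, replace = TRUE))
  )
  list(docs = docs, labels = rep(1:2, each = n_per_topic))
}
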
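mesh_dossier <- function() {
  pubs <- list(
    toy_record("1", mesh = c("Neoplasms", "Natural Language Processing")),
    toy_record("2", mesh = c("Rare Diseases"))
  )
  researcher_dossier("Dana Rivera", publications = pubs,
                     human_profile = "I study tumors with language models.")
}

test_that("prompt templates load from sectioned files and render one example", {
  tpl <- read_prompt_template(system.file("templates", "mesh.txt",
                                          package = "scholarprofiler"))
  expect_s3_class(tpl, "prompt_template")
  rendered <- render_prompt(tpl, "MATERIAL GOES HERE")
  expect_match(rendered, "Example input:")
  expect_match(rendered, "MATERIAL GOES HERE")
  # exactly one worked example in the rendered prompt
  expect_identical(lengths(regmatches(rendered,
    gregexpr("Example output:", rendered, fixed = TRUE))), 1L)
})

test_that("MeSH strategy buckets keywords and passes them to the backend once", {
  d <- mesh_dossier()
  v <- fixture_mesh_vocab()
  out <- generate_profile_mesh(d, backend_echo(), mesh_vocab = v)
  for (term in c("Neoplasms", "Natural Language Processing", "Rare Diseases")) {
    hits <- gregexpr(term, as.character(out), fixed = TRUE)[[1]]
    expect_identical(length(hits[hits > 0]), 1L)
  }
  expect_match(as.character(out), "Summarize each domain separately")
  expect_length(attr(out, "provenance"), 1L)

  bare <- researcher_dossier("Dana Rivera",
                             publications = list(toy_record("9")))
  expect_error(generate_profile_mesh(bare, backend_echo(), mesh_vocab = v),
               "no MeSH headings")
})

test_that("generation with the extractive backend is reproducible bit for bit", {
  d <- mesh_dossier()
  v <- fixture_mesh_vocab()
  a <- generate_profile_mesh(d, backend_extractive(), mesh_vocab = v)
  b <- generate_profile_mesh(d, backend_extractive(), mesh_vocab = v)
  expect_identical(as.character(a), as.character(b))
  x <- generate_profile_abstract(d, backend_extractive(), n_topics = 2L, seed = 4L)
  y <- generate_profile_abstract(d, backend_extractive(), n_topics = 2L, seed = 4L)
  expect_identical(as.character(x), as.character(y))
})

test_that("topic chunking recovers a planted partition and respects budgets", {
  set.seed(2)
  pc <- planted_corpus(n_per_topic = 3L, len = 30L, seed = 2L)
  pubs <- lapply(seq_along(pc$docs), function(i)
    toy_record(i, abstract = paste(pc$docs[[i]], collapse = " ")))
  groups <- chunk_abstracts_by_topic(pubs, n_topics = 2L,
                                     token_budget = 10000L, seed = 8L)
  expect_length(groups, 2L)
  got <- lapply(groups, function(g)
    sort(as.integer(vapply(g, function(p) p$pmid, character(1)))))
  expect_setequal(got, list(1:3, 4:6))
  # union of groups is the input set
  expect_setequal(unlist(got), 1:6)

  expect_length(chunk_abstracts_by_topic(pubs[1], 2L, 10000L, seed = 1L), 1L)
  expect_error(chunk_abstracts_by_topic(pubs, 2L, token_budget = 5L, seed = 1L),
               "token_budget")
  empty <- list(toy_record("e", abstract = ""))
  expect_error(chunk_abstracts_by_topic(empty, 2L, 100L, seed = 1L),
               "MeSH strategy")
})

test_that("divide-and-conquer costs one backend call per group plus one", {
  calls <- 0L
  counting <- generation_backend(
    generate = function(prompt, max_output_tokens = NULL) {
      calls <<- calls + 1L
      "summary text"
    }, deterministic = TRUE, name = "counting")
  d <- mesh_dossier()   # both pubs share one vocabulary -> usually 1-2 groups
  out <- generate_profile_abstract(d, counting, n_topics = 1L, seed = 3L)
  expect_identical(calls, 2L)  # one group + one combine
  expect_length(attr(out, "provenance"), 2L)

  calls <- 0L
  pc <- planted_corpus(n_per_topic = 3L, len = 30L, seed = 5L)
  pubs <- lapply(seq_along(pc$docs), function(i)
    toy_record(i, abstract = paste(pc$docs[[i]], collapse = " ")))
  d2 <- researcher_dossier("Dana Rivera", publications = pubs)
  invisible(generate_profile_abstract(d2, counting, n_topics = 2L, seed = 8L))
  expect_identical(calls, 3L)  # two groups + combine
})

test_that("extractive summaries only contain words from the input abstracts", {
  pc <- planted_corpus(n_per_topic = 3L, len = 25L, seed = 9L)
  pubs <- lapply(seq_along(pc$docs), function(i)
    toy_record(i, abstract = paste(pc$docs[[i]], collapse = " ")))
  d <- researcher_dossier("Dana Rivera", publications = pubs)
  out <- generate_profile_abstract(d, backend_extractive(), n_topics = 2L,
                                   seed = 8L)
  out_words <- setdiff(tokenize_words(as.character(out)), default_stopwords())
  in_words <- unlist(lapply(pubs, function(p) tokenize_words(p$abstract)))
  expect_true(all(out_words %in% in_words))
})

test_that("paraphrasing is the identity under the identity backend", {
  profile <- "My group studies viral evolution in wild bird populations."
  out <- paraphrase_profile(profile, backend_identity())
  expect_identical(as.character(out), profile)
  expect_error(paraphrase_profile("", backend_identity()), "non-empty")
  shuffled <- paraphrase_profile(profile, backend_shuffle(seed = 6L))
  expect_setequal(strsplit(as.character(shuffled), " ")[[1]],
                  strsplit(profile, " ")[[1]])
  expect_identical(sort(strsplit(as.character(shuffled), " ")[[1]]),
                   sort(strsplit(profile, " ")[[1]]))
})

test_that("prompts over the declared context limit are refused", {
  tiny <- generation_backend(
    generate = function(prompt, max_output_tokens = NULL) "x",
    context_limit = 10L, deterministic = TRUE, name = "tiny")
  d <- mesh_dossier()
  v <- fixture_mesh_vocab()
  expect_error(generate_profile_mesh(d, tiny, mesh_vocab = v),
               "context limit")
  # token counting uses the backend tokenizer when declared
  with_tok <- generation_backend(
    generate = function(prompt, max_output_tokens = NULL) "x",
    context_limit = 10L, tokenizer = function(text) 3L, name = "tok")
  expect_identical(count_tokens("one two three four", with_tok), 3L)
  expect_identical(count_tokens("one two three four"), as.integer(ceiling(4 * 1.3)))
})

test_that("backend failures carry the rendered prompt for debugging", {
  failing <- generation_backend(
    generate = function(prompt, max_output_tokens = NULL) stop("boom"),
    name = "failing")
  expect_error(paraphrase_profile("some profile", failing), "rendered prompt")
})
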
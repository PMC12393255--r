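test_that("efetch XML fixture parses with abstracts, MeSH names and years intact", {
  recs <- parse_pubmed_xml(system.file("extdata", "example_pubmed.xml",
                                       package = "scholarprofiler"))
  expect_length(recs, 3L)
  expect_identical(vapply(recs, function(r) r$pmid, character(1)),
                   c("1000001", "1000002", "1000003"))
  abstracts <- vapply(recs, function(r) r$abstract, character(1))
  expect_identical(sum(abstracts == ""), 1L)
  expect_identical(recs[[1]]$mesh_headings$descriptor,
                   c("Rare Diseases", "Natural Language Processing"))
  expect_identical(recs[[1]]$mesh_headings$major, c(TRUE, FALSE))
  # MedlineDate fallback
  expect_identical(recs[[3]]$pub_year, 2015L)
  # multi-part abstract concatenated
  expect_identical(recs[[3]]$abstract, "Background text. Results text.")
})

test_that("empty article set yields an empty list and malformed XML errors", {
  expect_identical(parse_pubmed_xml("<PubmedArticleSet/>"), list())
  expect_error(parse_pubmed_xml("<PubmedArticleSet><unclosed>"))
})

test_that("articles without a PMID are skipped with a warning", {
  xml <- paste0(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>No id</ArticleTitle>",
    "<AuthorList><Author><LastName>X</LastName><ForeName>Y</ForeName>",
    "</Author></AuthorList></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>")
  expect_warning(recs <- parse_pubmed_xml(xml), "PMID")
  expect_length(recs, 0L)
})

test_that("parse - serialize - parse round-trips preserve identity fields", {
  recs <- parse_pubmed_xml(system.file("extdata", "example_pubmed.xml",
                                       package = "scholarprofiler"))
  path <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_xml(recs, path)
  back <- parse_pubmed_xml(path)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$pmid, recs[[i]]$pmid)
    expect_identical(back[[i]]$pub_year, recs[[i]]$pub_year)
    expect_identical(back[[i]]$authors$surname, recs[[i]]$authors$surname)
    expect_identical(back[[i]]$mesh_headings$descriptor,
                     recs[[i]]$mesh_headings$descriptor)
  }
})

test_that("author position follows the first-three / last-three block rule", {
  # 2-author paper: author 2 is inside indices 1-3, hence first block
  r2 <- toy_record("1", surnames = c("Chen", "Rivera"),
                   givens = c("Li", "Dana"))
  expect_identical(author_position(r2, "Dana Rivera"), "first_block")

  ten <- paste0("S", 1:10)
  mk <- function(pos) {
    s <- ten; s[pos] <- "Rivera"
    toy_record("2", surnames = s, givens = rep("D", 10))
  }
  expect_identical(author_position(mk(8), "Dana Rivera"), "last_block")
  expect_identical(author_position(mk(5), "Dana Rivera"), "middle")
  expect_identical(author_position(mk(1), "Dana Rivera"), "first_block")
  expect_identical(author_position(r2, "Someone Else"), "absent")
  # given-initial mismatch is not a match
  expect_identical(author_position(mk(1), "Quentin Rivera"), "absent")
})

test_that("publication filter keeps the 10-year window and contributing positions", {
  years <- c(2010L, 2016L, 2020L, 2024L, 2024L)
  pubs <- lapply(seq_along(years), function(i)
    toy_record(i, year = years[i], surnames = c("Rivera", "Chen"),
               givens = c("Dana", "Li")))
  d <- researcher_dossier("Dana Rivera", publications = pubs)
  f <- filter_publications(d, reference_year = 2024L)
  expect_length(f$publications, 4L)
  expect_identical(vapply(f$publications, function(p) p$pub_year, integer(1)),
                   c(2016L, 2020L, 2024L, 2024L))
  # input unmodified, retained set a subset, and filtering idempotent
  expect_length(d$publications, 5L)
  expect_identical(filter_publications(f, reference_year = 2024L), f)

  mids <- lapply(1:3, function(i) {
    s <- paste0("S", 1:9); s[5] <- "Rivera"
    toy_record(i, year = 2020L, surnames = s, givens = rep("D", 9))
  })
  dm <- researcher_dossier("Dana Rivera", publications = mids)
  expect_length(filter_publications(dm, reference_year = 2024L)$publications, 0L)

  expect_error(filter_publications(d, reference_year = 2024L,
                                   window_years = 0L), "window_years")
})

test_that("the stricter rule keeps first block and senior author only", {
  s <- paste0("S", 1:10)
  s8 <- s; s8[8] <- "Rivera"       # last block but not senior
  s10 <- s; s10[10] <- "Rivera"    # senior
  pubs <- list(
    toy_record("a", year = 2020L, surnames = s8, givens = rep("D", 10)),
    toy_record("b", year = 2020L, surnames = s10, givens = rep("D", 10))
  )
  d <- researcher_dossier("Dana Rivera", publications = pubs)
  f <- filter_publications(d, reference_year = 2024L,
                           author_rule = "first3senior")
  expect_identical(vapply(f$publications, function(p) p$pmid, character(1)), "b")
})

test_that("records lacking a year are excluded with a warning", {
  pubs <- list(toy_record("1", year = 2020L),
               toy_record("2", year = NA_integer_))
  d <- researcher_dossier("Dana Rivera", publications = pubs)
  expect_warning(f <- filter_publications(d, reference_year = 2024L), "no year")
  expect_length(f$publications, 1L)
})

test_that("dossiers reject duplicate PMIDs and serialize through JSON", {
  expect_error(researcher_dossier("A B", publications = list(
    toy_record("1"), toy_record("1"))), "duplicate")
  d <- researcher_dossier("Dana Rivera", affiliation = "X",
                          publications = list(toy_record("1", mesh = "Neoplasms")),
                          human_profile = "I study tumors.")
  path <- withr::local_tempfile(fileext = ".json")
  dossiers_to_json(list(d), path)
  back <- dossiers_from_json(path)[[1]]
  expect_identical(back$name, d$name)
  expect_identical(back$human_profile, d$human_profile)
  expect_identical(back$publications[[1]]$pmid, "1")
  expect_identical(back$publications[[1]]$mesh_headings$descriptor, "Neoplasms")
})

test_that("MEDLINE flat text parses PMID, fields and MeSH", {
  lines <- c(
    "PMID- 42",
    "TI  - A study of things",
    "AB  - First part of the abstract",
    "      continued on the next line.",
    "FAU - Rivera, Dana",
    "FAU - Chen, Li",
    "MH  - *Neoplasms",
    "MH  - Machine Learning",
    "DP  - 2021 Mar"
  )
  rec <- parse_medline(lines)[[1]]
  expect_identical(rec$pmid, "42")
  expect_match(rec$abstract, "continued on the next line")
  expect_identical(rec$authors$surname, c("Rivera", "Chen"))
  expect_identical(rec$mesh_headings$descriptor,
                   c("Neoplasms", "Machine Learning"))
  expect_identical(rec$pub_year, 2021L)
})
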
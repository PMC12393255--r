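test_that("TF-IDF weights follow tf * ln(N/df) with stop-word removal", {
  w <- tfidf_weights(list(c("x", "x", "y"), c("y", "z")),
                     stop_words = character())
  # term in every doc weighs zero; doc-unique doubled term weighs 2 ln 2
  expect_equal(w[[1]][["x"]], 2 * log(2))
  expect_equal(w[[1]][["y"]], 0)
  expect_equal(w[[2]][["y"]], 0)
  expect_equal(w[[2]][["z"]], log(2))
  expect_error(tfidf_weights(list("only one doc")), ">= 2 documents")
  # a document of only stop words comes back empty
  w2 <- tfidf_weights(list("the and of", "cells grow"),
                      stop_words = c("the", "and", "of"))
  expect_length(w2[[1]], 0L)
})

test_that("distribution smoothing normalizes and respects the epsilon limit", {
  u <- to_distribution(c(a = 1, b = 1, c = 1, d = 1), letters[1:4])
  expect_equal(unname(u), rep(0.25, 4))
  z <- to_distribution(stats::setNames(numeric(), character()), letters[1:4])
  expect_equal(unname(z), rep(0.25, 4))
  lim <- to_distribution(c(a = 3, b = 1), c("a", "b"), epsilon = 1e-12)
  expect_equal(unname(lim), c(0.75, 0.25), tolerance = 1e-9)
  expect_error(to_distribution(c(a = 1), "a", epsilon = 0), "positive")
  expect_error(to_distribution(c(zz = 1), "a"), "cover")
})

test_that("KL divergence matches hand evaluation and Gibbs' inequality", {
  p <- c(a = 0.5, b = 0.5)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(a = 0.8, b = 0.2), c(a = 0.5, b = 0.5)),
               0.8 * log(1.6) + 0.2 * log(0.4))
  expect_error(kl_divergence(c(a = 1), c(b = 1)), "support")
  set.seed(31)
  for (rep in 1:50) {
    k <- sample(2:10, 1)
    pr <- stats::runif(k); pr <- stats::setNames(pr / sum(pr), paste0("t", 1:k))
    qr <- stats::runif(k); qr <- stats::setNames(qr / sum(qr), paste0("t", 1:k))
    expect_gte(kl_divergence(pr, qr), 0)
  }
})

test_that("profile KL is zero on identical texts and grows with vocabulary gap", {
  txt <- "genomic variants drive tumor progression in cohorts"
  expect_equal(profile_kl(txt, txt), 0)
  set.seed(5)
  a_words <- paste0("alpha", 1:20)
  b_words <- paste0("beta", 1:20)
  human <- paste(sample(a_words, 30, TRUE), collapse = " ")
  disjoint <- paste(sample(b_words, 30, TRUE), collapse = " ")
  half <- paste(sample(c(a_words, b_words), 30, TRUE), collapse = " ")
  # document frequencies come from the evaluation-run corpus, as in the
  # pipeline; a pair-only corpus would zero the idf of every shared term
  background <- replicate(10, paste(sample(c(a_words, b_words), 30, TRUE),
                                    collapse = " "))
  kl_disjoint <- profile_kl(human, disjoint, corpus = background)
  kl_half <- profile_kl(human, half, corpus = background)
  expect_gt(kl_disjoint, kl_half)

  batch <- profile_kl_batch(rep(txt, 3), rep(txt, 3))
  expect_equal(batch$mean, 0)
  expect_equal(batch$variance, 0)
  expect_warning(na_kl <- profile_kl("the and", "cells grow",
                                     stop_words = c("the", "and")),
                 "stop-word")
  expect_true(is.na(na_kl))
})

test_that("both KL directions and the symmetrized mean are available", {
  h <- "alpha alpha beta"
  m <- "beta gamma gamma"
  fwd <- profile_kl(h, m, stop_words = character())
  bwd <- profile_kl(h, m, stop_words = character(),
                    direction = "machine_vs_human")
  sym <- profile_kl(h, m, stop_words = character(), direction = "symmetric")
  expect_equal(sym, (fwd + bwd) / 2)
  # tf mode runs and differs from tf-idf mode in general
  expect_gte(profile_kl(h, m, stop_words = character(), mode = "tf"), 0)
})

test_that("novel-term counting recovers planted MeSH concepts only", {
  v <- fixture_mesh_vocab()
  human <- paste("We pioneered work on rare diseases and computational",
                 "linguistics with tumors plus madeupword anotherfake")
  machine <- c("A profile about machine learning.",
               "Another text mentioning tumors here.")
  res <- novel_term_count(human, machine, mesh_vocab = v)
  # tumors appears in a machine text; the two fake words match no MeSH term
  expect_setequal(res$terms, c("rare diseases", "computational linguistics"))
  expect_identical(res$count, 2L)

  sub <- novel_term_count("rare diseases", "all about rare diseases",
                          mesh_vocab = v)
  expect_identical(sub$count, 0L)
  all_count <- novel_term_count(human, character(), mesh_vocab = v)
  expect_setequal(all_count$terms,
                  c("rare diseases", "computational linguistics", "tumors"))
})

test_that("novel-term count is antitone in the machine-text corpus", {
  v <- fixture_mesh_vocab()
  pool <- c("rare diseases", "cancer", "nlp", "machine learning",
            "orphan diseases", "random words", "more filler")
  set.seed(17)
  for (rep in 1:30) {
    human <- paste(sample(pool, 5, TRUE), collapse = " ")
    machines <- replicate(2, paste(sample(pool, 4, TRUE), collapse = " "))
    before <- novel_term_count(human, machines, mesh_vocab = v)$count
    extra <- paste(sample(pool, 4, TRUE), collapse = " ")
    after <- novel_term_count(human, c(machines, extra), mesh_vocab = v)$count
    expect_lte(after, before)
  }
})

test_that("BERTScore is exact on identities and hand-placed unit vectors", {
  expect_equal(bert_score(c("a", "b", "c"), c("a", "b", "c")),
               c(precision = 1, recall = 1, f1 = 1))
  # candidate {c} at angle 0 to r1 and 60 degrees to r2:
  # P = max over refs = 1; R = mean(1, cos 60) = 0.75
  emb <- function(tokens) {
    lookup <- rbind(c = c(1, 0), r1 = c(1, 0),
                    r2 = c(cos(pi / 3), sin(pi / 3)))
    lookup[tokens, , drop = FALSE]
  }
  b <- bert_score("c", c("r1", "r2"), embedder = emb)
  expect_equal(unname(b["precision"]), 1)
  expect_equal(unname(b["recall"]), 0.75)
  expect_equal(unname(b["f1"]), 2 * 1 * 0.75 / 1.75)
  expect_warning(z <- bert_score(character(), "a"), "empty")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("BERTScore P/F1 ignore reference order and R ignores candidate order", {
  embedder <- random_projection_embedder(seed = 9L)
  set.seed(41)
  for (rep in 1:10) {
    cand <- paste0("w", sample(30, 5))
    ref <- paste0("w", sample(30, 6))
    base <- bert_score(cand, ref, embedder)
    perm_ref <- bert_score(cand, sample(ref), embedder)
    perm_cand <- bert_score(sample(cand), ref, embedder)
    expect_equal(perm_ref[["precision"]], base[["precision"]])
    expect_equal(perm_ref[["f1"]], base[["f1"]])
    expect_equal(perm_cand[["recall"]], base[["recall"]])
  }
})

test_that("the random-projection embedder is deterministic and unit-norm", {
  e1 <- random_projection_embedder(seed = 3L)
  e2 <- random_projection_embedder(seed = 3L)
  m1 <- e1(c("tumor", "genome"))
  expect_identical(m1, e2(c("tumor", "genome")))
  expect_equal(unname(rowSums(m1^2)), c(1, 1))
  e3 <- random_projection_embedder(seed = 4L)
  expect_false(identical(m1, e3(c("tumor", "genome"))))
  # embedding a token must not disturb the session RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(e1("newtoken")); after <- stats::runif(1)
  expect_identical(before, after)
})
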
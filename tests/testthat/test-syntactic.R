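test_that("dependency depth counts edges on chains, stars and singletons", {
  single <- parsed_sentence("hi", "INTJ", 1L, "root")
  expect_identical(dependency_depth(single), 0L)
  expect_identical(dependency_depth(chain_sentence(5)), 4L)
  expect_identical(dependency_depth(star_sentence(6)), 1L)
  expect_identical(dependency_depth(star_sentence(6), count = "nodes"), 2L)
})

test_that("invalid head graphs are rejected", {
  expect_error(parsed_sentence(c("a", "b"), c("X", "X"), c(2L, 1L),
                               c("dep", "dep")), "root")
  expect_error(parsed_sentence(c("a", "b", "c"), rep("X", 3), c(1L, 3L, 2L),
                               rep("dep", 3)), "tree|root")
  expect_error(parsed_sentence("a", "X", 5L, "root"), "root|range")
})

test_that("syntactic complexity is the mean non-root path length", {
  expect_equal(syntactic_complexity(star_sentence(7)), 1.0)
  expect_equal(syntactic_complexity(chain_sentence(5)), (1 + 2 + 3 + 4) / 4)
  expect_equal(syntactic_complexity(parsed_sentence("go", "VERB", 1L, "root")), 0)
  # complexity never exceeds max depth
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(2:9, 1)
    head <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    s <- parsed_sentence(paste0("t", 1:n), rep("NOUN", n), head,
                         c("root", rep("dep", n - 1L)))
    expect_lte(syntactic_complexity(s), dependency_depth(s))
  }
})

test_that("attachment ambiguity scores hand-built modifier phrases", {
  # no adpositional or clausal modifier at all
  expect_equal(syntactic_ambiguity(chain_sentence(4)), 0)
  # verb + noun before a 2-token adpositional phrase -> one span of length 2
  expect_equal(syntactic_ambiguity(vnpn_sentence()), 2.0)
  # two qualifying spans of lengths 2 and 4 average to 3
  s <- parsed_sentence(
    form = c("saw", "man", "with", "scope", "during", "the", "long", "night"),
    upos = c("VERB", "NOUN", "ADP", "NOUN", "ADP", "DET", "ADJ", "NOUN"),
    head = c(1L, 1L, 4L, 2L, 8L, 8L, 8L, 1L),
    deprel = c("root", "obj", "case", "nmod", "case", "det", "amod", "obl")
  )
  expect_equal(syntactic_ambiguity(s), 3.0)
  # a single preceding attachment site is unambiguous
  s1 <- parsed_sentence(
    form = c("slept", "on", "mats"),
    upos = c("VERB", "ADP", "NOUN"),
    head = c(1L, 3L, 1L),
    deprel = c("root", "case", "obl")
  )
  expect_equal(syntactic_ambiguity(s1), 0)
})

test_that("PoS distribution percentages and lexical diversity tally tokens", {
  s <- parsed_sentence(c("cells", "divide", "fast", "cells"),
                       c("NOUN", "VERB", "ADV", "NOUN"),
                       c(2L, 2L, 2L, 2L), c("nsubj", "root", "advmod", "obj"))
  pd <- pos_distribution(list(s))
  expect_equal(pd[["NOUN"]], 50)
  expect_equal(pd[["VERB"]], 25)
  expect_equal(sum(pd), 100)
  ld <- lexical_diversity(list(s))
  expect_identical(ld[["NOUN"]], 1L)  # "cells" twice, one distinct form
  run <- parsed_sentence(c("Run", "run", "running"), rep("VERB", 3),
                         c(1L, 1L, 1L), c("root", "dep", "dep"))
  expect_identical(lexical_diversity(list(run))[["VERB"]], 2L)
  expect_identical(lexical_diversity(list()),
                   stats::setNames(integer(), character()))
  expect_error(pos_distribution(list()), "tokens")
})

test_that("CoNLL-U input round-trips into parsed sentences", {
  lines <- c(
    "# sent_id = 1",
    "1\tsaw\tsee\tVERB\t_\t_\t0\troot\t_\t_",
    "2\tman\tman\tNOUN\t_\t_\t1\tobj\t_\t_",
    "3\twith\twith\tADP\t_\t_\t4\tcase\t_\t_",
    "4\tscope\tscope\tNOUN\t_\t_\t2\tnmod\t_\t_",
    "",
    "1\thello\thello\tINTJ\t_\t_\t0\troot\t_\t_"
  )
  sents <- read_conllu(lines)
  expect_length(sents, 2L)
  expect_identical(sents[[1]]$form, c("saw", "man", "with", "scope"))
  expect_identical(dependency_depth(sents[[1]]), 3L)
  expect_equal(syntactic_ambiguity(sents[[1]]), 2.0)
})

test_that("document profiles aggregate sentence means, order-invariantly", {
  sents <- list(star_sentence(4), chain_sentence(3), vnpn_sentence())
  prof <- syntactic_profile(sentences = sents)
  expect_equal(prof$max_dep_depth, mean(c(1, 2, 3)))
  expect_equal(prof$syntactic_complexity, mean(c(1, 1.5, 2)))
  expect_equal(prof$syntactic_ambiguity, mean(c(0, 0, 2)))
  expect_equal(sum(prof$pos_distribution), 100)
  shuffled <- syntactic_profile(sentences = sents[c(3, 1, 2)])
  expect_equal(shuffled$max_dep_depth, prof$max_dep_depth)
  expect_equal(shuffled$pos_distribution[sort(names(prof$pos_distribution))],
               prof$pos_distribution[sort(names(prof$pos_distribution))])
  # single star sentence composes the trivial profile
  one <- syntactic_profile(sentences = list(star_sentence(5)))
  expect_equal(one$syntactic_complexity, 1.0)
  expect_equal(one$max_dep_depth, 1)
  expect_equal(one$syntactic_ambiguity, 0)
})

test_that("a planted depth difference is detected by the paired t-test", {
  set.seed(61)
  n_docs <- 30L
  shallow <- vapply(seq_len(n_docs), function(i) {
    syntactic_profile(sentences = lapply(1:3, function(j)
      chain_sentence(sample(3:5, 1))))$max_dep_depth
  }, numeric(1))
  deep <- vapply(seq_len(n_docs), function(i) {
    syntactic_profile(sentences = lapply(1:3, function(j)
      chain_sentence(sample(4:6, 1))))$max_dep_depth
  }, numeric(1))
  res <- paired_t_test(deep, shallow)
  expect_true(res$significant)
  expect_lt(res$p, 0.05)
})
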
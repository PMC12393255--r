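#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions the generator emulates: per-researcher
#' publication counts drawn from realistic band frequencies, planted topic
#' structure with controllable vocabulary separation, MeSH headings sampled
#' from per-topic descriptor pools, human-style profiles carrying planted
#' novel MeSH terms absent from every abstract, and multi-rater Likert
#' tables with a controlled agreement level. Defaults mirror a mid-sized
#' academic-medical faculty corpus: publication-count bands
#' 0-29/30-59/60-89/90-119/120+ with frequencies 41/56/29/12/29 over 167
#' researchers, a 48.8% stable / 4.3% shifting topic-stability mix, three
#' raters per item on a 5-point scale, and a 10-year window ending at the
#' reference year.
#'
#' @param seed Global seed; all substreams derive from it.
#' @param n_researchers Number of researchers.
#' @param pubs_band_weights Sampling weights of the five publication-count
#'   bands `0-29, 30-59, 60-89, 90-119, 120-149`.
#' @param pubs_range Optional `c(min, max)` overriding the band draw with a
#'   uniform count (handy for small test corpora).
#' @param n_topics Number of planted topics.
#' @param topic_vocab_size Content words per topic vocabulary.
#' @param topic_overlap Fraction of each topic's vocabulary shared with a
#'   common pool (0 = fully disjoint, separable topics).
#' @param abstract_length Tokens per synthetic abstract.
#' @param stable_fraction,shifting_fraction Fractions of researchers planted
#'   with a single dominant topic versus one distinct topic per publication;
#'   the remainder mix a few topics.
#' @param novel_terms_per_profile Planted novel MeSH terms per human
#'   profile (terms in the MeSH vocabulary, never in any abstract).
#' @param profile_prob Probability a researcher has a human-written profile.
#' @param agreement Rating-table agreement level in `[0, 1]`: probability a
#'   rater copies the item's latent category.
#' @param n_items Items in the synthetic rating table.
#' @param n_categories Likert categories, default 5.
#' @param n_raters Raters per item, default 3.
#' @param reference_year,window_years Publication-year window.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_researchers = 20L,
                         pubs_band_weights = c(41, 56, 29, 12, 29),
                         pubs_range = NULL,
                         n_topics = 5L, topic_vocab_size = 40L,
                         topic_overlap = 0, abstract_length = 60L,
                         stable_fraction = 0.488, shifting_fraction = 0.043,
                         novel_terms_per_profile = 3L, profile_prob = 1,
                         agreement = 0.9, n_items = 60L, n_categories = 5L,
                         n_raters = 3L, reference_year = 2024L,
                         window_years = 10L) {
  cfg <- list(seed = as.integer(seed), n_researchers = as.integer(n_researchers),
              pubs_band_weights = pubs_band_weights, pubs_range = pubs_range,
              n_topics = as.integer(n_topics),
              topic_vocab_size = as.integer(topic_vocab_size),
              topic_overlap = topic_overlap,
              abstract_length = as.integer(abstract_length),
              stable_fraction = stable_fraction,
              shifting_fraction = shifting_fraction,
              novel_terms_per_profile = as.integer(novel_terms_per_profile),
              profile_prob = profile_prob, agreement = agreement,
              n_items = as.integer(n_items), n_categories = as.integer(n_categories),
              n_raters = as.integer(n_raters),
              reference_year = as.integer(reference_year),
              window_years = as.integer(window_years))
  stopifnot(cfg$n_researchers > 0L, cfg$n_topics > 0L,
            cfg$topic_vocab_size > 0L, cfg$novel_terms_per_profile >= 0L,
            cfg$n_items > 0L, cfg$n_raters > 0L, cfg$n_categories >= 2L,
            cfg$topic_overlap >= 0, cfg$topic_overlap <= 1,
            cfg$stable_fraction >= 0, cfg$shifting_fraction >= 0,
            cfg$stable_fraction + cfg$shifting_fraction <= 1,
            cfg$agreement >= 0, cfg$agreement <= 1,
            cfg$profile_prob >= 0, cfg$profile_prob <= 1)
  structure(cfg, class = "synth_config")
}

# one global seed fans out to fixed per-component substreams so adding a
# component never shifts existing draws
substream_seed <- function(cfg, offset) {
  (cfg$seed * 1009L + offset) %% 2147483647L
}

synth_word <- function(topic, j) sprintf("topic%02dterm%03d", topic, j)

# per-topic vocabularies; overlapping share is replaced by a common pool
synth_vocabularies <- function(cfg) {
  n_shared <- floor(cfg$topic_vocab_size * cfg$topic_overlap)
  shared <- if (n_shared > 0) sprintf("sharedterm%03d", seq_len(n_shared)) else character()
  lapply(seq_len(cfg$n_topics), function(k) {
    own <- synth_word(k, seq_len(cfg$topic_vocab_size - n_shared))
    c(own, shared)
  })
}

# per-topic MeSH descriptor pools + a reserved pool of novel descriptors;
# methodology/health tree branches alternate so categorize_mesh has work to do
synth_mesh_vocabulary <- function(cfg) {
  n_desc_per_topic <- 5L
  descriptors <- character()
  trees <- list()
  for (k in seq_len(cfg$n_topics)) {
    for (j in seq_len(n_desc_per_topic)) {
      descriptors <- c(descriptors, sprintf("Topic%02d Descriptor%02d", k, j))
      branch <- if (j %% 2L == 0L) sprintf("E%02d.%03d", k, j) else sprintf("C%02d.%03d", k, j)
      trees[[length(trees) + 1L]] <- branch
    }
  }
  n_novel_pool <- 60L  # fixed reserve; over-demanding configs must error
  novel <- sprintf("Novelconcept%03d", seq_len(n_novel_pool))
  for (j in seq_len(n_novel_pool)) trees[[length(trees) + 1L]] <- sprintf("C99.%03d", j)
  new_mesh_vocabulary(c(descriptors, novel), trees)
}

# uniform integer in [lo, hi], safe when lo == hi
sample_int_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

synth_pub_count <- function(cfg) {
  if (!is.null(cfg$pubs_range)) {
    return(sample_int_range(cfg$pubs_range[1], cfg$pubs_range[2]))
  }
  band <- sample.int(5L, 1L, prob = cfg$pubs_band_weights)
  lo <- c(1L, 30L, 60L, 90L, 120L)[band]
  hi <- c(29L, 59L, 89L, 119L, 149L)[band]
  sample_int_range(lo, hi)
}

#' Generate a synthetic researcher corpus with planted structure
#'
#' Draws bag-of-words abstracts from planted per-topic vocabularies, samples
#' MeSH headings from per-topic descriptor pools present in the returned
#' MeSH vocabulary, places each researcher in first/last/middle authorship
#' positions, spreads years over the configured window, and builds
#' human-style profiles from topic keywords plus planted novel MeSH terms
#' that occur in no abstract. Ground truth (per-publication topic, planted
#' novel terms, stable/shifting label, authorship positions) is returned in
#' a machine-readable sidecar so downstream tests never re-derive it.
#'
#' @param cfg A [synth_config()].
#' @return List with `dossiers` (list of [researcher_dossier()]),
#'   `mesh_vocab` (the fixture `mesh_vocabulary`), and `truth` (list with
#'   per-researcher labels, per-publication topics, planted novel terms).
#' @export
make_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  vocabs <- synth_vocabularies(cfg)
  mesh_vocab <- synth_mesh_vocabulary(cfg)
  novel_pool <- grep("^Novelconcept", mesh_vocab$descriptors, value = TRUE)
  if (cfg$novel_terms_per_profile > length(novel_pool)) {
    stop("novel_terms_per_profile exceeds the reserved novel-term pool",
         call. = FALSE)
  }
  set.seed(substream_seed(cfg, 11L))
  n_stable <- round(cfg$n_researchers * cfg$stable_fraction)
  n_shift <- round(cfg$n_researchers * cfg$shifting_fraction)
  labels <- c(rep("stable", n_stable), rep("shifting", n_shift),
              rep("intermediate", cfg$n_researchers - n_stable - n_shift))
  dossiers <- vector("list", cfg$n_researchers)
  truth <- vector("list", cfg$n_researchers)
  years <- seq(cfg$reference_year - cfg$window_years + 1L, cfg$reference_year)
  filler_surnames <- c("Smith", "Chen", "Garcia", "Okafor", "Ivanov", "Patel",
                       "Kim", "Mueller", "Rossi", "Tanaka")
  for (r in seq_len(cfg$n_researchers)) {
    set.seed(substream_seed(cfg, 100L + r))
    label <- labels[r]
    n_pubs <- synth_pub_count(cfg)
    if (label == "stable") {
      n_pubs <- max(n_pubs, 4L)  # a single topic over >= 4 pubs keeps diversity < 0.3
      topics <- rep(sample.int(cfg$n_topics, 1L), n_pubs)
    } else if (label == "shifting") {
      n_pubs <- min(n_pubs, cfg$n_topics)
      topics <- sample.int(cfg$n_topics, n_pubs)  # all distinct: diversity 1
    } else {
      k <- max(2L, min(cfg$n_topics, ceiling(n_pubs * 0.5)))
      topics <- sample(sample.int(cfg$n_topics, k), n_pubs, replace = TRUE)
    }
    name <- sprintf("Alex Researcher%03d", r)
    affil <- "Synthetic Medical Center"
    pubs <- vector("list", n_pubs)
    positions <- character(n_pubs)
    for (i in seq_len(n_pubs)) {
      topic <- topics[i]
      abstract <- paste(sample(vocabs[[topic]], cfg$abstract_length,
                               replace = TRUE), collapse = " ")
      pos_kind <- sample(c("first", "last", "middle"), 1L,
                         prob = c(0.4, 0.4, 0.2))
      # a middle position needs at least 7 authors to exist at all
      n_auth <- if (pos_kind == "middle") sample_int_range(7L, 9L) else
        sample_int_range(4L, 9L)
      others <- tibble::tibble(
        surname = sample(filler_surnames, n_auth - 1L, replace = TRUE),
        given = sample(LETTERS, n_auth - 1L, replace = TRUE),
        affiliation = "Elsewhere Institute"
      )
      self <- tibble::tibble(surname = sprintf("Researcher%03d", r),
                             given = "Alex", affiliation = affil)
      at <- switch(pos_kind,
                   first = sample_int_range(1L, min(3L, n_auth)),
                   last = n_auth,
                   middle = sample_int_range(4L, n_auth - 3L))
      authors <- dplyr::bind_rows(
        if (at > 1L) others[seq_len(at - 1L), ] else NULL,
        self,
        if (at < n_auth) others[seq(at, n_auth - 1L), ] else NULL
      )
      desc_pool <- grep(sprintf("^Topic%02d ", topic),
                        mesh_vocab$descriptors, value = TRUE)
      mesh <- sample(desc_pool, min(3L, length(desc_pool)))
      pubs[[i]] <- publication_record(
        pmid = sprintf("%03d%04d", r, i),
        title = paste("Study of", synth_word(topic, 1L)),
        abstract = abstract,
        authors = authors,
        mesh_headings = tibble::tibble(descriptor = mesh,
                                       major = seq_along(mesh) == 1L),
        pub_year = years[sample.int(length(years), 1L)]
      )
      positions[i] <- pos_kind
    }
    has_profile <- stats::runif(1) < cfg$profile_prob
    novel_terms <- character()
    profile <- NULL
    if (has_profile) {
      novel_terms <- sample(novel_pool, cfg$novel_terms_per_profile)
      topic_words <- unique(unlist(lapply(unique(topics), function(k)
        vocabs[[k]][1:5])))
      profile <- paste(
        "My research focuses on", paste(topic_words, collapse = ", "),
        "with emerging interests in",
        paste(tolower(novel_terms), collapse = ", "), "."
      )
    }
    dossiers[[r]] <- researcher_dossier(name = name, affiliation = affil,
                                        publications = pubs,
                                        human_profile = profile)
    truth[[r]] <- list(name = name, label = label, topics = topics,
                       positions = positions, novel_terms = tolower(novel_terms))
  }
  # middle-author-only pubs are filtered out downstream; intermediate
  # researchers keep planted diversity by construction, not guarantee
  n_pubs_planted <- vapply(truth, function(t) length(t$topics), integer(1))
  list(dossiers = dossiers, mesh_vocab = mesh_vocab,
       truth = list(researchers = truth,
                    labels = stats::setNames(labels, vapply(truth, `[[`,
                                                            character(1), "name")),
                    n_pubs = n_pubs_planted,
                    config = unclass(cfg)))
}

#' Generate a synthetic multi-rater rating table
#'
#' Each item has a latent category drawn uniformly; each of the raters
#' copies the latent category with probability `agreement` and otherwise
#' draws uniformly from the remaining categories. With agreement 1 the table
#' shows perfect agreement; at agreement `1/Q` ratings are uniform and AC1
#' concentrates near zero.
#'
#' @param cfg A [synth_config()].
#' @return List with `table` (a [rating_table()]) and `truth` (latent
#'   categories and the agreement level).
#' @export
make_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(substream_seed(cfg, 977L))
  q <- cfg$n_categories
  latent <- sample.int(q, cfg$n_items, replace = TRUE)
  counts <- matrix(0L, nrow = cfg$n_items, ncol = q)
  for (i in seq_len(cfg$n_items)) {
    for (rater in seq_len(cfg$n_raters)) {
      pick <- if (stats::runif(1) < cfg$agreement) latent[i] else
        sample(setdiff(seq_len(q), latent[i]), 1L)
      counts[i, pick] <- counts[i, pick] + 1L
    }
  }
  list(table = rating_table(counts),
       truth = list(latent = latent, agreement = cfg$agreement))
}

#' Write a synthetic corpus to disk in its interchange formats
#'
#' Publications go to PubMed-style efetch XML, the MeSH fixture vocabulary
#' to descriptor XML, dossier metadata (profiles included) to JSON, and the
#' ground truth to a JSON sidecar.
#'
#' @param corpus Result of [make_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_pubs <- unlist(lapply(corpus$dossiers, function(d) d$publications),
                     recursive = FALSE)
  write_pubmed_xml(all_pubs, file.path(dir, "publications.xml"))
  write_mesh_xml(corpus$mesh_vocab, file.path(dir, "mesh.xml"))
  dossiers_to_json(corpus$dossiers, file.path(dir, "dossiers.json"))
  writeLines(jsonlite::toJSON(corpus$truth, auto_unbox = TRUE, digits = NA),
             file.path(dir, "truth.json"))
  invisible(dir)
}
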
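#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation over tokenized abstracts, fit with a
#' collapsed Gibbs sampler (compiled). The seed is mandatory and drives
#' R's RNG, so the same seed and corpus always give identical topic
#' assignments. Stop words are removed before fitting. Thirty topics is
#' the default used for corpus-wide stability analyses; callers grouping a
#' single researcher's publications typically pass a smaller value.
#'
#' @param corpus List of documents (character scalars or token vectors);
#'   must be non-empty. A warning is raised when the corpus is smaller than
#'   `n_topics`.
#' @param n_topics Number of topics, default 30.
#' @param seed Integer seed (required).
#' @param alpha Document-topic Dirichlet concentration, default 0.1. The
#'   sparse prior reflects that a short abstract usually expresses one or
#'   two topics, which is what dominant-topic assignment relies on.
#' @param eta Topic-word Dirichlet concentration, default 0.1.
#' @param n_iter Gibbs sweeps, default 500.
#' @param stop_words Stop-word vector removed before fitting.
#' @return Object of class `lda_model` with elements `n_topics`, `phi`
#'   (topic-word probabilities), `theta` (training doc-topic
#'   distributions), `vocab`, `seed`, `alpha`, `eta`, `n_iter`,
#'   `corpus_fingerprint`.
#' @export
fit_lda <- function(corpus, n_topics = 30L, seed, alpha = 0.1,
                    eta = 0.1, n_iter = 500L,
                    stop_words = default_stopwords()) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (missing(seed)) stop("seed is required for a reproducible fit", call. = FALSE)
  n_topics <- as.integer(n_topics)
  if (length(corpus) < n_topics) {
    warning("corpus smaller than n_topics (", length(corpus), " < ", n_topics,
            "); topics will be underdetermined", call. = FALSE)
  }
  tok_docs <- lapply(corpus, function(d) {
    toks <- if (is.character(d) && length(d) == 1L) tokenize_words(d) else as.character(d)
    toks[!toks %in% stop_words]
  })
  vocab <- sort(unique(unlist(tok_docs)))
  if (length(vocab) == 0L) stop("corpus empty after stop-word removal", call. = FALSE)
  doc_idx <- integer()
  word_idx <- integer()
  for (i in seq_along(tok_docs)) {
    w <- match(tok_docs[[i]], vocab)
    doc_idx <- c(doc_idx, rep(i, length(w)))
    word_idx <- c(word_idx, w)
  }
  set.seed(as.integer(seed))
  fit <- lda_gibbs(doc_idx - 1L, word_idx - 1L, length(tok_docs),
                   length(vocab), n_topics, alpha, eta, as.integer(n_iter))
  ndk <- fit$ndk
  nkw <- fit$nkw
  theta <- (ndk + alpha) / (rowSums(ndk) + n_topics * alpha)
  phi <- (nkw + eta) / (rowSums(nkw) + length(vocab) * eta)
  colnames(phi) <- vocab
  structure(list(
    n_topics = n_topics, phi = phi, theta = theta, vocab = vocab,
    seed = as.integer(seed), alpha = alpha, eta = eta,
    n_iter = as.integer(n_iter),
    corpus_fingerprint = c(n_docs = length(tok_docs),
                           n_tokens = length(word_idx),
                           n_vocab = length(vocab))
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", x$n_topics, "topics over",
      x$corpus_fingerprint[["n_docs"]], "docs /",
      x$corpus_fingerprint[["n_vocab"]], "terms ( seed", x$seed, ")\n")
  invisible(x)
}

#' Topic distribution of a document under a fitted model
#'
#' For a training document (given by integer index) the Gibbs-estimated
#' distribution is returned. For a new document (token vector or text) the
#' posterior over topics is computed from the fitted topic-word
#' probabilities under a single-topic-proportion approximation:
#' `p(k | doc) ~ alpha_k * prod_w phi[k, w]`, evaluated in log space.
#' Out-of-vocabulary tokens are ignored.
#'
#' @param model An `lda_model`.
#' @param doc Training-document index, token vector, or text.
#' @param stop_words Stop words removed from new documents.
#' @return Numeric probability vector of length `n_topics` (sums to 1).
#' @export
doc_topic_distribution <- function(model, doc,
                                   stop_words = default_stopwords()) {
  if (is.numeric(doc) && length(doc) == 1L) {
    return(model$theta[as.integer(doc), ])
  }
  toks <- if (is.character(doc) && length(doc) == 1L) tokenize_words(doc) else as.character(doc)
  toks <- toks[!toks %in% stop_words]
  w <- match(toks, model$vocab)
  w <- w[!is.na(w)]
  log_p <- log(rep(1 / model$n_topics, model$n_topics))
  if (length(w) > 0L) {
    log_p <- log_p + rowSums(log(model$phi[, w, drop = FALSE]))
  }
  log_p <- log_p - max(log_p)
  p <- exp(log_p)
  p / sum(p)
}

#' Dominant topic of a document
#'
#' Argmax of the document-topic distribution; ties break toward the lowest
#' topic index.
#'
#' @inheritParams doc_topic_distribution
#' @return 1-based topic index.
#' @export
dominant_topic <- function(model, doc, stop_words = default_stopwords()) {
  which.max(doc_topic_distribution(model, doc, stop_words))
}

diversity_band <- function(diversity) {
  if (diversity < 0.3) "stable" else if (diversity > 0.7) "shifting" else "intermediate"
}

#' Topic-diversity score for one researcher
#'
#' Number of unique dominant topics divided by number of publications with
#' usable abstracts. Low values mean the researcher keeps publishing in the
#' same topics; a score below 0.3 is classed stable and above 0.7 shifting
#' (scores exactly at a threshold are intermediate). Publications without
#' abstracts are excluded from both numerator and denominator and tallied.
#'
#' @param model An `lda_model`.
#' @param pubs List of [publication_record()] objects.
#' @param id Researcher identifier carried into the output.
#' @param stop_words Stop words for new-document inference.
#' @return One-row tibble: `id`, `n_pubs`, `n_unique_topics`, `diversity`,
#'   `band`, `n_excluded`.
#' @export
diversity_score <- function(model, pubs, id = NA_character_,
                            stop_words = default_stopwords()) {
  has_abs <- vapply(pubs, function(p) nzchar(p$abstract), logical(1))
  usable <- pubs[has_abs]
  if (length(usable) == 0L) {
    stop("no publications with non-empty abstracts", call. = FALSE)
  }
  topics <- vapply(usable, function(p)
    dominant_topic(model, p$abstract, stop_words), integer(1))
  div <- length(unique(topics)) / length(topics)
  tibble::tibble(
    id = id, n_pubs = length(usable),
    n_unique_topics = length(unique(topics)),
    diversity = div, band = diversity_band(div),
    n_excluded = sum(!has_abs)
  )
}

#' Year-by-topic publication counts per researcher
#'
#' Long-format table of dominant-topic counts by researcher and publication
#' year, the data behind a per-researcher topic-stability heatmap. Topic
#' assignment is year-independent; the year only groups the display. The
#' per-(researcher, year) marginal over topics equals that year's
#' publication count.
#'
#' @param model An `lda_model`.
#' @param dossiers List of [researcher_dossier()] objects.
#' @param stop_words Stop words for new-document inference.
#' @return Tibble with columns `researcher`, `year`, `topic`, `n`.
#' @export
topic_year_table <- function(model, dossiers,
                             stop_words = default_stopwords()) {
  rows <- purrr::map(dossiers, function(d) {
    pubs <- Filter(function(p) nzchar(p$abstract) && !is.na(p$pub_year),
                   d$publications)
    if (length(pubs) == 0L) return(NULL)
    tibble::tibble(
      researcher = d$name,
      year = vapply(pubs, function(p) p$pub_year, integer(1)),
      topic = vapply(pubs, function(p)
        dominant_topic(model, p$abstract, stop_words), integer(1))
    )
  })
  df <- dplyr::bind_rows(rows)
  if (nrow(df) == 0L) {
    return(tibble::tibble(researcher = character(), year = integer(),
                          topic = integer(), n = integer()))
  }
  dplyr::count(df, .data$researcher, .data$year, .data$topic, name = "n")
}
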
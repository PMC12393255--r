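#' Default English stop-word list
#'
#' Read from the plain-text list shipped with the package (one token per
#' line). Stop words are removed before TF-IDF weighting and novel-term
#' counting, since function words carry no information about research focus.
#'
#' @return Character vector of lower-cased stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "scholarprofiler")
  readLines(path, warn = FALSE)
}

#' TF-IDF term weights over a small corpus
#'
#' Raw term frequency times `ln(N / df)`, with `N` the corpus size and `df`
#' the number of documents containing the term; no add-one smoothing, so a
#' term present in every document weighs exactly zero. Stop words are
#' removed before counting.
#'
#' @param docs List of documents, each a character scalar (tokenized
#'   internally) or a token vector. At least two documents are required,
#'   since document frequency is meaningless on a single-document corpus.
#' @param stop_words Character vector of tokens to drop; default the
#'   packaged English list.
#' @return List of named numeric vectors (term -> weight), one per document,
#'   named by document index or by `names(docs)`.
#' @export
tfidf_weights <- function(docs, stop_words = default_stopwords()) {
  if (length(docs) < 2L) {
    stop("tfidf_weights needs >= 2 documents: document frequency is ",
         "undefined on a single-document corpus", call. = FALSE)
  }
  tok_docs <- lapply(docs, function(d) {
    toks <- if (is.character(d) && length(d) == 1L) tokenize_words(d) else as.character(d)
    toks[!toks %in% stop_words]
  })
  n <- length(tok_docs)
  df_tab <- table(unlist(lapply(tok_docs, unique)))
  idf <- log(n / as.numeric(df_tab))
  names(idf) <- names(df_tab)
  out <- lapply(tok_docs, function(toks) {
    if (length(toks) == 0L) return(stats::setNames(numeric(), character()))
    tf <- table(toks)
    w <- as.numeric(tf) * idf[names(tf)]
    stats::setNames(as.numeric(w), names(tf))
  })
  if (!is.null(names(docs))) names(out) <- names(docs)
  out
}

#' Turn a weight vector into a smoothed probability distribution
#'
#' Adds `epsilon` to the weight of every vocabulary term (terms absent from
#' the vector get weight 0 first) and renormalizes to sum 1. The smoothing
#' keeps KL divergence finite when the two compared documents have
#' non-overlapping support.
#'
#' @param v Named numeric vector of non-negative term weights.
#' @param vocabulary Character vector of terms; must cover the support of `v`.
#' @param epsilon Additive smoothing mass per term; must be positive.
#' @return Named numeric probability vector over `vocabulary`.
#' @export
to_distribution <- function(v, vocabulary, epsilon = 1e-9) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("epsilon must be a positive number", call. = FALSE)
  }
  vocabulary <- unique(vocabulary)
  if (!all(names(v) %in% vocabulary)) {
    stop("vocabulary must cover the support of the weight vector", call. = FALSE)
  }
  w <- stats::setNames(rep(0, length(vocabulary)), vocabulary)
  w[names(v)] <- v
  w <- w + epsilon
  w / sum(w)
}

#' Kullback-Leibler divergence between two term distributions
#'
#' `D(p || q) = sum p(t) ln(p(t) / q(t))` in nats; terms with `p(t) = 0`
#' contribute nothing. The two distributions must live on the same support
#' (same term set), which in practice is the union vocabulary of the
#' compared pair.
#'
#' @param p,q Named numeric probability vectors over identical term sets.
#' @return Non-negative divergence in nats.
#' @export
kl_divergence <- function(p, q) {
  if (!setequal(names(p), names(q)) || length(p) != length(q)) {
    stop("p and q must share an identical support", call. = FALSE)
  }
  q <- q[names(p)]
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

profile_distribution_pair <- function(human, machine, corpus, stop_words,
                                      epsilon, mode) {
  docs <- c(list(human = human, machine = machine), as.list(corpus))
  if (mode == "tf") {
    tok <- lapply(docs[1:2], function(d) {
      toks <- if (length(d) == 1L && is.character(d)) tokenize_words(d) else as.character(d)
      toks[!toks %in% stop_words]
    })
    weights <- lapply(tok, function(t) {
      if (length(t) == 0L) stats::setNames(numeric(), character()) else {
        tf <- table(t); stats::setNames(as.numeric(tf), names(tf))
      }
    })
  } else {
    weights <- tfidf_weights(docs, stop_words = stop_words)[1:2]
  }
  if (length(weights[[1]]) == 0L || length(weights[[2]]) == 0L) return(NULL)
  vocab <- union(names(weights[[1]]), names(weights[[2]]))
  list(p = to_distribution(weights[[1]], vocab, epsilon),
       q = to_distribution(weights[[2]], vocab, epsilon))
}

#' Vocabulary-shift KL divergence between a human and a machine profile
#'
#' Weights both profiles by TF-IDF against a shared corpus (the profile
#' documents of the evaluation run), smooths them into distributions over
#' the union vocabulary of the pair, and returns the KL divergence. The
#' human-written profile is the reference distribution by default: the
#' divergence measures how far the machine profile's vocabulary falls short
#' of covering it. Large values mean the two profiles foreground different
#' keywords.
#'
#' @param human,machine Profile texts.
#' @param corpus Additional corpus texts for document-frequency computation;
#'   the two profiles are always included.
#' @param stop_words Stop-word vector.
#' @param epsilon Smoothing mass, default `1e-9`.
#' @param direction `"human_vs_machine"` (default), `"machine_vs_human"`, or
#'   `"symmetric"` (mean of both directions).
#' @param mode `"tfidf"` (default) weights terms by TF-IDF before
#'   normalizing; `"tf"` uses raw term frequencies.
#' @return KL divergence in nats, or `NA` with a warning when either profile
#'   is empty after stop-word removal.
#' @export
profile_kl <- function(human, machine, corpus = character(),
                       stop_words = default_stopwords(), epsilon = 1e-9,
                       direction = c("human_vs_machine", "machine_vs_human",
                                     "symmetric"),
                       mode = c("tfidf", "tf")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  pq <- profile_distribution_pair(human, machine, corpus, stop_words,
                                  epsilon, mode)
  if (is.null(pq)) {
    warning("profile empty after stop-word removal; KL undefined", call. = FALSE)
    return(NA_real_)
  }
  switch(direction,
    human_vs_machine = kl_divergence(pq$p, pq$q),
    machine_vs_human = kl_divergence(pq$q, pq$p),
    symmetric = (kl_divergence(pq$p, pq$q) + kl_divergence(pq$q, pq$p)) / 2
  )
}

#' Batch KL divergence across researcher profile pairs
#'
#' Computes [profile_kl()] for every pair, using all supplied texts as the
#' shared document-frequency corpus, and summarizes with the mean and the
#' population variance across pairs.
#'
#' @param humans,machines Equal-length character vectors of profile texts.
#' @param ids Optional identifiers.
#' @inheritParams profile_kl
#' @return List with `scores` (tibble: id, kl), `mean`, and `variance`
#'   (population variance over the non-missing values).
#' @export
profile_kl_batch <- function(humans, machines, ids = NULL,
                             stop_words = default_stopwords(), epsilon = 1e-9,
                             direction = "human_vs_machine", mode = "tfidf") {
  stopifnot(length(humans) == length(machines), length(humans) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(humans))
  corpus <- c(humans, machines)
  kl <- vapply(seq_along(humans), function(i) {
    profile_kl(humans[i], machines[i], corpus = corpus[-c(i, length(humans) + i)],
               stop_words = stop_words, epsilon = epsilon,
               direction = direction, mode = mode)
  }, numeric(1))
  ok <- !is.na(kl)
  list(
    scores = tibble::tibble(id = ids, kl = kl),
    mean = mean(kl[ok]),
    variance = if (any(ok)) mean((kl[ok] - mean(kl[ok]))^2) else NA_real_
  )
}

#' Count novel MeSH concepts unique to the human-written profile
#'
#' Terms of the human profile that carry a zero TF-IDF weight in every
#' machine-generated text - operationally, stop-word-filtered terms absent
#' from all machine texts - restricted to recognized MeSH descriptors or
#' entry terms so that only words indicative of conceptual originality are
#' counted. Multi-word MeSH phrases are found by a longest-match scan.
#'
#' @param human Human-written profile text (non-empty).
#' @param machine_texts Character vector of machine-generated texts (may be
#'   empty, in which case every MeSH-matching human term counts).
#' @param stop_words Stop-word vector.
#' @param mesh_vocab A `mesh_vocabulary`.
#' @return List with `count` and `terms` (normalized matched phrases).
#' @export
novel_term_count <- function(human, machine_texts,
                             stop_words = default_stopwords(), mesh_vocab) {
  stopifnot(is.character(human), length(human) == 1L, nzchar(human))
  toks <- tokenize_words(human)
  toks_kept <- toks[!toks %in% stop_words]
  phrases <- unique(mesh_match_terms(toks_kept, mesh_vocab))
  if (length(phrases) == 0L) return(list(count = 0L, terms = character()))
  machine_joined <- vapply(machine_texts, function(m) {
    mt <- tokenize_words(m)
    paste0(" ", paste(vapply(mt, normalize_mesh_term, character(1)),
                      collapse = " "), " ")
  }, character(1))
  novel <- phrases[vapply(phrases, function(ph) {
    needle <- paste0(" ", ph, " ")
    !any(vapply(machine_joined, function(mj)
      grepl(needle, mj, fixed = TRUE), logical(1)))
  }, logical(1))]
  list(count = length(novel), terms = novel)
}

#' Deterministic random-projection token embedder
#'
#' Maps each token to a fixed unit vector drawn from a seeded Gaussian
#' keyed by a polynomial hash of the token, so identical tokens always get
#' identical embeddings, across sessions and platforms, without any model
#' download. Intended as the offline default for [bert_score()]; a
#' contextual-model adapter can be supplied instead through the same
#' contract (`function(tokens) -> matrix` with one row per token).
#'
#' @param dim Embedding dimension, default 64.
#' @param seed Integer seed mixed into every token hash.
#' @return A function of contract `function(tokens) -> numeric matrix`.
#' @export
random_projection_embedder <- function(dim = 64L, seed = 42L) {
  force(dim); force(seed)
  cache <- new.env(parent = emptyenv())
  token_vec <- function(tok) {
    if (exists(tok, envir = cache, inherits = FALSE)) {
      return(get(tok, envir = cache, inherits = FALSE))
    }
    h <- 0
    for (b in utf8ToInt(tok)) h <- (h * 131 + b) %% 2147483563
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed((h + seed * 7919) %% 2147483647)
    v <- stats::rnorm(dim)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    v <- v / sqrt(sum(v^2))
    assign(tok, v, envir = cache)
    v
  }
  function(tokens) {
    if (length(tokens) == 0L) return(matrix(numeric(), nrow = 0, ncol = dim))
    t(vapply(as.character(tokens), token_vec, numeric(dim)))
  }
}

#' BERTScore-style greedy embedding similarity
#'
#' Embeds both token sequences, computes all pairwise cosine similarities,
#' and greedily matches each token to its best counterpart: recall is the
#' mean over reference tokens of their maximum cosine against the candidate,
#' precision the symmetric quantity over candidate tokens, and F1 their
#' harmonic mean. No idf weighting and no baseline rescaling are applied.
#'
#' @param candidate,reference Token vectors (or untokenized strings).
#' @param embedder Embedding provider, `function(tokens) -> matrix` with one
#'   row per token; default [random_projection_embedder()].
#' @return Named numeric vector `c(precision, recall, f1)`; zeros with a
#'   warning when either sequence is empty.
#' @export
bert_score <- function(candidate, reference,
                       embedder = random_projection_embedder()) {
  cand <- as_tokens(candidate)
  ref <- as_tokens(reference)
  if (length(cand) == 0L || length(ref) == 0L) {
    warning("empty sequence; BERTScore defined as 0", call. = FALSE)
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  ce <- embedder(cand)
  re <- embedder(ref)
  norm_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), .Machine$double.eps)
  sim <- norm_rows(ce) %*% t(norm_rows(re))   # candidate x reference
  p <- mean(apply(sim, 1, max))
  r <- mean(apply(sim, 2, max))
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}
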
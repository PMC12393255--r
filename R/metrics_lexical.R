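#' Tokenize text into lower-cased word tokens
#'
#' Lower-cases, strips punctuation (keeping intra-word characters only),
#' and splits on whitespace. This is the default tokenizer for every lexical
#' and vocabulary metric in the package; all of them operate on token
#' vectors, so an alternative tokenization can be supplied by tokenizing
#' upstream.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_words <- function(text) {
  if (length(text) != 1L || is.na(text)) return(character())
  x <- tolower(text)
  x <- gsub("[^a-z0-9' -]", " ", x)
  x <- gsub("[-']", " ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

as_tokens <- function(x) {
  if (length(x) == 1L && (is.na(x) || grepl("\\s", x) || !nzchar(x))) {
    tokenize_words(x)
  } else as.character(x)
}

ngram_counts <- function(tokens, n) {
  m <- length(tokens) - n + 1L
  if (m < 1L) return(integer())
  grams <- tokens[seq_len(m)]
  if (n > 1L) {
    for (k in 2:n) grams <- paste(grams, tokens[k:(m + k - 1L)], sep = "")
  }
  u <- unique(grams)
  stats::setNames(tabulate(match(grams, u), length(u)), u)
}

#' BLEU score for a single candidate/reference pair
#'
#' The original corpus-free sentence form: geometric mean of clipped n-gram
#' precisions for n = 1..`max_n`, times the brevity penalty
#' `exp(1 - r/c)` applied when the candidate is shorter than the reference.
#' Without smoothing (the default) any zero n-gram precision zeroes the
#' whole score, as in the original definition; `smooth = TRUE` adds one to
#' every numerator and denominator instead.
#'
#' @param candidate,reference Token vectors (or untokenized strings, which
#'   are passed through [tokenize_words()]).
#' @param max_n Longest n-gram order, default 4.
#' @param smooth Apply add-one smoothing to the n-gram precisions.
#' @return Score in `[0, 1]`. Empty candidate or reference scores 0 with a
#'   warning.
#' @export
bleu_score <- function(candidate, reference, max_n = 4L, smooth = FALSE) {
  cand <- as_tokens(candidate)
  ref <- as_tokens(reference)
  if (length(cand) == 0L || length(ref) == 0L) {
    warning("empty candidate or reference; BLEU defined as 0", call. = FALSE)
    return(0)
  }
  log_p <- numeric(max_n)
  for (n in seq_len(max_n)) {
    cc <- ngram_counts(cand, n)
    if (length(cc) == 0L) {
      # candidate shorter than n: no n-grams to score
      if (!smooth) return(0)
      log_p[n] <- log(1 / 1)
      next
    }
    rc <- ngram_counts(ref, n)
    ref_side <- as.integer(rc[names(cc)])
    ref_side[is.na(ref_side)] <- 0L
    clipped <- sum(pmin(as.integer(cc), ref_side))
    total <- sum(cc)
    if (smooth) {
      clipped <- clipped + 1L
      total <- total + 1L
    }
    if (clipped == 0L) return(0)
    log_p[n] <- log(clipped / total)
  }
  bp <- if (length(cand) < length(ref)) exp(1 - length(ref) / length(cand)) else 1
  bp * exp(mean(log_p))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_row <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_row[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L precision, recall and F for a candidate/reference pair
#'
#' Longest-common-subsequence overlap: precision = LCS / candidate length,
#' recall = LCS / reference length, F the beta-weighted harmonic mean
#' `(1 + b^2) P R / (R + b^2 P)` (0 when both P and R are 0).
#'
#' @inheritParams bleu_score
#' @param beta Recall weight in the F measure, default 1.
#' @return Named numeric vector `c(precision, recall, f)`. Empty inputs give
#'   zeros with a warning.
#' @export
rouge_l <- function(candidate, reference, beta = 1) {
  stopifnot(beta > 0)
  cand <- as_tokens(candidate)
  ref <- as_tokens(reference)
  if (length(cand) == 0L || length(ref) == 0L) {
    warning("empty candidate or reference; ROUGE-L defined as 0", call. = FALSE)
    return(c(precision = 0, recall = 0, f = 0))
  }
  l <- lcs_length(cand, ref)
  p <- l / length(cand)
  r <- l / length(ref)
  f <- if (p + r == 0) 0 else (1 + beta^2) * p * r / (r + beta^2 * p)
  c(precision = p, recall = r, f = f)
}

# Monotone in-order unigram alignment for one stage: pairs the k-th
# unmatched candidate occurrence of a word with the k-th unmatched reference
# occurrence. Deterministic; see the methods vignette for why this stands in
# for the original minimum-crossing search.
align_stage <- function(cand_keys, ref_keys, cand_free, ref_free) {
  pairs <- matrix(integer(), ncol = 2)
  used_ref <- !ref_free
  for (i in which(cand_free)) {
    j <- which(!used_ref & ref_keys == cand_keys[i] & !is.na(ref_keys) &
                 !is.na(cand_keys[i]))
    if (length(j) > 0L) {
      pairs <- rbind(pairs, c(i, j[1]))
      used_ref[j[1]] <- TRUE
    }
  }
  pairs
}

#' METEOR score for a candidate/reference pair
#'
#' Staged unigram alignment (exact match, then optional stem match, then
#' optional synonym match), harmonic mean weighted toward recall
#' `F = P R / (alpha P + (1 - alpha) R)`, and a fragmentation penalty
#' `gamma * (chunks / matches)^beta_pen`, where chunks are maximal runs of
#' matches contiguous and order-consistent in both sequences. The final
#' score is `F * (1 - penalty)`.
#'
#' @inheritParams bleu_score
#' @param alpha Precision weight in the harmonic mean, default 0.9.
#' @param beta_pen Fragmentation exponent, default 3.
#' @param gamma Fragmentation weight, default 0.5.
#' @param stemmer Optional `function(tokens) -> tokens` mapping words to
#'   stems for the second alignment stage; `NULL` disables the stage.
#' @param synonyms Optional `function(token) -> character()` returning a
#'   synonym set for the third stage; `NULL` (default) disables it, as no
#'   lexical database is shipped.
#' @return Score in `[0, 1]`; 0 when there are no matches.
#' @export
meteor_score <- function(candidate, reference, alpha = 0.9, beta_pen = 3,
                         gamma = 0.5, stemmer = NULL, synonyms = NULL) {
  cand <- as_tokens(candidate)
  ref <- as_tokens(reference)
  if (length(cand) == 0L || length(ref) == 0L) {
    warning("empty candidate or reference; METEOR defined as 0", call. = FALSE)
    return(0)
  }
  cand_free <- rep(TRUE, length(cand))
  ref_free <- rep(TRUE, length(ref))
  pairs <- align_stage(cand, ref, cand_free, ref_free)
  take <- function(pairs) {
    if (nrow(pairs) > 0L) {
      cand_free[pairs[, 1]] <<- FALSE
      ref_free[pairs[, 2]] <<- FALSE
    }
  }
  take(pairs)
  all_pairs <- pairs
  if (!is.null(stemmer) && any(cand_free) && any(ref_free)) {
    st_pairs <- align_stage(stemmer(cand), stemmer(ref), cand_free, ref_free)
    take(st_pairs)
    all_pairs <- rbind(all_pairs, st_pairs)
  }
  if (!is.null(synonyms) && any(cand_free) && any(ref_free)) {
    # synonym stage: a candidate token matches any reference token in its
    # synonym set, earliest reference occurrence first
    for (i in which(cand_free)) {
      cand_set <- c(cand[i], synonyms(cand[i]))
      j <- which(ref_free & ref %in% cand_set)
      if (length(j) > 0L) {
        all_pairs <- rbind(all_pairs, c(i, j[1]))
        cand_free[i] <- FALSE
        ref_free[j[1]] <- FALSE
      }
    }
  }
  m <- nrow(all_pairs)
  if (m == 0L) return(0)
  p <- m / length(cand)
  r <- m / length(ref)
  f_mean <- p * r / (alpha * p + (1 - alpha) * r)
  ord <- all_pairs[order(all_pairs[, 1]), , drop = FALSE]
  chunks <- 1L
  if (m > 1L) {
    for (k in 2:m) {
      if (!(ord[k, 1] == ord[k - 1L, 1] + 1L && ord[k, 2] == ord[k - 1L, 2] + 1L)) {
        chunks <- chunks + 1L
      }
    }
  }
  penalty <- gamma * (chunks / m)^beta_pen
  f_mean * (1 - penalty)
}

#' Score a batch of candidate/reference pairs with all lexical metrics
#'
#' @param candidates,references Character vectors of equal positive length;
#'   each element is a full text (tokenized internally).
#' @param ids Optional identifier column (defaults to position).
#' @param ... Passed on to the individual metrics.
#' @return List with `scores` (tibble: one row per pair with `bleu`,
#'   `rouge_l_precision/recall/f`, `meteor`) and `means` (named numeric of
#'   column means).
#' @export
score_pairs <- function(candidates, references, ids = NULL, ...) {
  stopifnot(length(candidates) == length(references), length(candidates) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(candidates))
  rows <- purrr::map2(candidates, references, function(cand, ref) {
    ct <- tokenize_words(cand)
    rt <- tokenize_words(ref)
    rl <- rouge_l(ct, rt)
    tibble::tibble(
      bleu = bleu_score(ct, rt, ...),
      rouge_l_precision = rl[["precision"]],
      rouge_l_recall = rl[["recall"]],
      rouge_l_f = rl[["f"]],
      meteor = meteor_score(ct, rt)
    )
  })
  scores <- dplyr::bind_rows(rows)
  scores <- dplyr::bind_cols(tibble::tibble(id = ids), scores)
  means <- colMeans(scores[-1])
  list(scores = scores, means = means)
}
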
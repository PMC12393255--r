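#' Construct a parsed sentence
#'
#' A dependency-parsed sentence: one row per token with surface form,
#' Universal PoS tag, head index and dependency label. Exactly one token is
#' the root and points at itself; the head graph must form a single tree.
#'
#' @param form Character vector of surface forms.
#' @param upos Universal PoS tags (NOUN, VERB, ADP, ...), same length.
#' @param head Integer head indices (1-based); the root token's head is its
#'   own index. A head of 0 is also accepted (CoNLL-U convention) and
#'   rewritten to the self-loop form.
#' @param deprel Dependency labels, same length.
#' @return An object of class `parsed_sentence` (a tibble).
#' @export
parsed_sentence <- function(form, upos, head, deprel) {
  n <- length(form)
  stopifnot(n >= 1L, length(upos) == n, length(head) == n, length(deprel) == n)
  head <- as.integer(head)
  root <- which(head == 0L | head == seq_len(n))
  if (length(root) != 1L) {
    stop("a parsed sentence must have exactly one root token", call. = FALSE)
  }
  head[root] <- root
  if (any(head < 1L | head > n)) stop("head index out of range", call. = FALSE)
  s <- tibble::tibble(form = as.character(form), upos = as.character(upos),
                      head = head, deprel = as.character(deprel))
  class(s) <- c("parsed_sentence", class(s))
  validate_tree(s)
  s
}

# depth of every token (root = 0); errors on cycles / disconnection
token_depths <- function(s) {
  n <- nrow(s)
  depth <- rep(NA_integer_, n)
  root <- which(s$head == seq_len(n))
  depth[root] <- 0L
  for (iter in seq_len(n)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0L) return(depth)
    ready <- todo[!is.na(depth[s$head[todo]])]
    if (length(ready) == 0L) break
    depth[ready] <- depth[s$head[ready]] + 1L
  }
  if (anyNA(depth)) {
    stop("head graph is not a single tree (cycle or unreachable token)",
         call. = FALSE)
  }
  depth
}

validate_tree <- function(s) invisible(token_depths(s))

#' Maximum dependency-tree depth of a sentence
#'
#' The maximum number of edges on a root-to-token path; a single-token
#' sentence has depth 0. Set `count = "nodes"` to count nodes instead,
#' which shifts every depth by one.
#'
#' @param s A [parsed_sentence()].
#' @param count `"edges"` (default) or `"nodes"`.
#' @return Integer depth.
#' @export
dependency_depth <- function(s, count = c("edges", "nodes")) {
  count <- match.arg(count)
  d <- max(token_depths(s))
  if (count == "nodes") d + 1L else d
}

#' Syntactic complexity of a sentence
#'
#' Mean root-to-token path length over all non-root tokens, in edges. A
#' star-shaped parse scores 1; deeper nesting pushes the mean up toward the
#' tree depth. A single-token sentence scores 0 by convention.
#'
#' @inheritParams dependency_depth
#' @return Non-negative real.
#' @export
syntactic_complexity <- function(s, count = c("edges", "nodes")) {
  count <- match.arg(count)
  d <- token_depths(s)
  root <- which(s$head == seq_len(nrow(s)))[1]
  d <- d[seq_len(nrow(s)) != root]
  if (length(d) == 0L) return(0)
  if (count == "nodes") d <- d + 1L
  mean(d)
}

subtree_indices <- function(s, i) {
  n <- nrow(s)
  in_sub <- rep(FALSE, n)
  in_sub[i] <- TRUE
  repeat {
    grow <- !in_sub & in_sub[s$head] & s$head != seq_len(n)
    if (!any(grow)) break
    in_sub[grow] <- TRUE
  }
  which(in_sub)
}

# dependency labels whose subtrees count as attachment-ambiguous modifier
# phrases: adpositional phrases and relative/participial/adverbial clauses
ambiguous_modifier_labels <- function() {
  c("nmod", "obl", "acl", "acl:relcl", "advcl")
}

#' Mean length of attachment-ambiguous modifier phrases
#'
#' Identifies maximal modifier phrases - subtrees headed by a token whose
#' dependency label marks an adpositional phrase or a relative, participial
#' or adverbial clause - that are preceded in the sentence by at least two
#' plausible attachment sites (NOUN, PROPN, VERB or AUX tokens outside the
#' phrase). Such phrases could attach to more than one earlier head, the
#' classic attachment ambiguity. Returns the mean token length of these
#' phrases, or 0 when the sentence has none. Nested qualifying modifiers are
#' not double-counted: only maximal phrases (not contained in another
#' qualifying phrase) are measured.
#'
#' @param s A [parsed_sentence()].
#' @param labels Dependency labels treated as modifier-phrase heads.
#' @return Non-negative real.
#' @export
syntactic_ambiguity <- function(s, labels = ambiguous_modifier_labels()) {
  validate_tree(s)
  n <- nrow(s)
  heads_mask <- s$upos %in% c("NOUN", "PROPN", "VERB", "AUX")
  cand <- which(s$deprel %in% labels)
  if (length(cand) == 0L) return(0)
  # keep only maximal modifiers: drop candidates inside another candidate's subtree
  subtrees <- lapply(cand, function(i) subtree_indices(s, i))
  names(subtrees) <- as.character(cand)
  maximal <- vapply(seq_along(cand), function(k) {
    !any(vapply(seq_along(cand), function(j)
      j != k && cand[k] %in% subtrees[[j]], logical(1)))
  }, logical(1))
  lens <- c()
  for (k in which(maximal)) {
    span <- subtrees[[k]]
    start <- min(span)
    n_sites <- sum(heads_mask[seq_len(n) < start & !(seq_len(n) %in% span)])
    if (n_sites >= 2L) lens <- c(lens, length(span))
  }
  if (length(lens) == 0L) 0 else mean(lens)
}

#' PoS tag distribution over a set of sentences
#'
#' @param sentences List of [parsed_sentence()] objects with >= 1 token in
#'   total.
#' @return Named numeric vector of frequency percentages (sums to 100).
#' @export
pos_distribution <- function(sentences) {
  tags <- unlist(lapply(sentences, function(s) s$upos))
  if (length(tags) == 0L) stop("no tokens to tabulate", call. = FALSE)
  tab <- table(tags)
  stats::setNames(as.numeric(tab) / sum(tab) * 100, names(tab))
}

#' Lexical diversity per PoS tag
#'
#' Number of distinct lower-cased surface forms per tag.
#'
#' @param sentences List of [parsed_sentence()] objects (may be empty).
#' @return Named integer vector.
#' @export
lexical_diversity <- function(sentences) {
  if (length(sentences) == 0L) return(stats::setNames(integer(), character()))
  df <- dplyr::bind_rows(lapply(sentences, function(s)
    tibble::tibble(upos = s$upos, form = tolower(s$form))))
  if (nrow(df) == 0L) return(stats::setNames(integer(), character()))
  agg <- dplyr::summarise(dplyr::group_by(df, .data$upos),
                          n = dplyr::n_distinct(.data$form), .groups = "drop")
  stats::setNames(as.integer(agg$n), agg$upos)
}

#' Read CoNLL-U formatted parses
#'
#' Minimal reader: comment lines and multi-word/empty-token ranges are
#' skipped; columns FORM (2), UPOS (4), HEAD (7) and DEPREL (8) are used.
#'
#' @param source Path to a CoNLL-U file, or a character vector of lines.
#' @return List of [parsed_sentence()] objects.
#' @export
read_conllu <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  sentences <- list()
  buf <- list()
  flush <- function() {
    if (length(buf) == 0L) return()
    m <- do.call(rbind, buf)
    sentences[[length(sentences) + 1L]] <<- parsed_sentence(
      form = m[, 1], upos = m[, 2], head = as.integer(m[, 3]), deprel = m[, 4])
    buf <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || grepl("[.-]", f[1])) next
    buf[[length(buf) + 1L]] <- c(f[2], f[4], f[7], f[8])
  }
  flush()
  sentences
}

#' A degenerate sentence parser for plumbing runs
#'
#' Splits text on sentence punctuation and produces flat star parses (every
#' token attached to the first token, tagged `X`). It carries no linguistic
#' signal and exists so the full pipeline can run end-to-end without a
#' parsing model; real analyses should supply CoNLL-U parses or a genuine
#' parser through the same contract (`function(text) -> list of
#' parsed_sentence`).
#'
#' @return A parser function.
#' @export
parser_flat <- function() {
  function(text) {
    sents <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    sents <- sents[nzchar(trimws(sents))]
    out <- list()
    for (sent in sents) {
      toks <- tokenize_words(sent)
      if (length(toks) == 0L) next
      out[[length(out) + 1L]] <- parsed_sentence(
        form = toks, upos = rep("X", length(toks)),
        head = c(1L, rep(1L, length(toks) - 1L)),
        deprel = c("root", rep("dep", max(0L, length(toks) - 1L)))
      )
    }
    out
  }
}

#' Five-dimension syntactic profile of a document
#'
#' Aggregates PoS distribution, mean maximum dependency depth, mean
#' syntactic complexity, mean attachment-ambiguity span length, and lexical
#' diversity over all sentences of a document. Scalar measures are sentence
#' means; sentences the parser fails on are skipped with a warning and
#' tallied.
#'
#' @param text Document text (ignored when `sentences` is given).
#' @param parser Parser contract `function(text) -> list of parsed_sentence`.
#' @param sentences Pre-parsed sentences, e.g. from [read_conllu()].
#' @return List of class `syntactic_profile` with fields `pos_distribution`,
#'   `max_dep_depth`, `syntactic_complexity`, `syntactic_ambiguity`,
#'   `lexical_diversity`, `n_sentences`, `n_skipped`.
#' @export
syntactic_profile <- function(text = NULL, parser = NULL, sentences = NULL) {
  if (is.null(sentences)) {
    stopifnot(!is.null(text), !is.null(parser))
    sentences <- parser(text)
  }
  depths <- numeric()
  complexities <- numeric()
  ambiguities <- numeric()
  kept <- list()
  skipped <- 0L
  for (s in sentences) {
    res <- tryCatch({
      list(d = dependency_depth(s), c = syntactic_complexity(s),
           a = syntactic_ambiguity(s))
    }, error = function(e) {
      warning("sentence skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) { skipped <- skipped + 1L; next }
    depths <- c(depths, res$d)
    complexities <- c(complexities, res$c)
    ambiguities <- c(ambiguities, res$a)
    kept[[length(kept) + 1L]] <- s
  }
  if (length(kept) == 0L) stop("no parsable sentences in document", call. = FALSE)
  structure(list(
    pos_distribution = pos_distribution(kept),
    max_dep_depth = mean(depths),
    syntactic_complexity = mean(complexities),
    syntactic_ambiguity = mean(ambiguities),
    lexical_diversity = lexical_diversity(kept),
    n_sentences = length(kept),
    n_skipped = skipped
  ), class = "syntactic_profile")
}

#' @export
print.syntactic_profile <- function(x, ...) {
  cat("<syntactic_profile>", x$n_sentences, "sentences (", x$n_skipped,
      "skipped )\n")
  cat(sprintf("  mean max depth %.3f | complexity %.3f | ambiguity %.3f\n",
              x$max_dep_depth, x$syntactic_complexity, x$syntactic_ambiguity))
  invisible(x)
}
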
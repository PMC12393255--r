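#' Load a MeSH descriptor vocabulary
#'
#' Parses MeSH descriptor XML (the `desc*.xml` dialect distributed by the
#' NLM) into a case-insensitive vocabulary of descriptor names, their entry
#' terms, and their tree numbers. The tree numbers place each descriptor
#' under one or more lettered branches (C diseases, E analytical techniques,
#' L information science, ...), which drives the methodology/health keyword
#' split used by MeSH-based profile generation.
#'
#' @param source Path, raw vector or literal XML string of descriptor XML.
#' @return An object of class `mesh_vocabulary`.
#' @export
load_mesh_vocabulary <- function(source) {
  doc <- xml2::read_xml(source)
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  names <- character(length(recs))
  trees <- vector("list", length(recs))
  entry <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    names[i] <- xml2::xml_text(
      xml2::xml_find_first(r, "./DescriptorName/String"))
    trees[[i]] <- xml2::xml_text(
      xml2::xml_find_all(r, "./TreeNumberList/TreeNumber"))
    entry[[i]] <- unique(xml2::xml_text(
      xml2::xml_find_all(r, ".//ConceptList/Concept/TermList/Term/String")))
  }
  new_mesh_vocabulary(names, trees, entry)
}

#' Construct a MeSH vocabulary from in-memory components
#'
#' Primarily for the synthetic-corpus generator and tests; real vocabularies
#' come from [load_mesh_vocabulary()].
#'
#' @param descriptors Character vector of descriptor names.
#' @param tree_numbers List of character vectors, one per descriptor.
#' @param entry_terms List of character vectors of entry terms per descriptor
#'   (the descriptor name itself is always included).
#' @return An object of class `mesh_vocabulary`.
#' @export
new_mesh_vocabulary <- function(descriptors, tree_numbers = NULL,
                                entry_terms = NULL) {
  stopifnot(length(descriptors) > 0L)
  n <- length(descriptors)
  if (is.null(tree_numbers)) tree_numbers <- rep(list(character()), n)
  if (is.null(entry_terms)) entry_terms <- rep(list(character()), n)
  stopifnot(length(tree_numbers) == n, length(entry_terms) == n)
  term_map <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (term in unique(c(descriptors[i], entry_terms[[i]]))) {
      key <- normalize_mesh_term(term)
      if (!nzchar(key)) next
      assign(key, descriptors[i], envir = term_map)
    }
  }
  trees <- stats::setNames(tree_numbers, descriptors)
  max_len <- max(vapply(ls(term_map), function(k)
    length(strsplit(k, " ", fixed = TRUE)[[1]]), integer(1)))
  structure(
    list(descriptors = descriptors, tree_numbers = trees,
         entry_terms = stats::setNames(entry_terms, descriptors),
         term_map = term_map, max_phrase_len = max_len),
    class = "mesh_vocabulary"
  )
}

# lower-case, hyphens to spaces, collapse whitespace
normalize_mesh_term <- function(term) {
  x <- tolower(term)
  x <- gsub("[-/]", " ", x)
  x <- gsub("[^a-z0-9 ]", "", x)
  trimws(gsub("\\s+", " ", x))
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat("<mesh_vocabulary>", length(x$descriptors), "descriptors,",
      length(ls(x$term_map)), "lookup terms\n")
  invisible(x)
}

#' Look up a term in a MeSH vocabulary
#'
#' Matching is case-insensitive over descriptor names and entry terms, with
#' hyphen/space normalization.
#'
#' @param vocab A `mesh_vocabulary`.
#' @param term Term or phrase to look up.
#' @return The canonical descriptor name, or `NA_character_` if absent.
#' @export
mesh_lookup <- function(vocab, term) {
  key <- normalize_mesh_term(term)
  if (nzchar(key) && exists(key, envir = vocab$term_map, inherits = FALSE)) {
    get(key, envir = vocab$term_map, inherits = FALSE)
  } else NA_character_
}

#' Tree numbers of a descriptor
#' @param vocab A `mesh_vocabulary`.
#' @param descriptor Canonical descriptor name.
#' @return Character vector of tree numbers (may be empty).
#' @export
mesh_tree_numbers <- function(vocab, descriptor) {
  tn <- vocab$tree_numbers[[descriptor]]
  if (is.null(tn)) character() else tn
}

#' Split MeSH keywords into methodology and health buckets
#'
#' MeSH-based profile generation prompts the backend to summarize the
#' methodological and the health-domain vocabulary of a researcher
#' separately. The split is driven by MeSH tree branches: a term with any
#' tree number under the health branches (default C diseases, F psychiatry/
#' psychology, G phenomena and processes) goes to the health bucket, which
#' takes precedence because profiles foreground health topics; a term whose
#' tree numbers all fall under the methodology branches (default E
#' analytical/diagnostic techniques, L information science, V publication
#' characteristics) goes to the methodology bucket; anything else - or any
#' term absent from the vocabulary, which additionally raises a warning - is
#' left unassigned. The three buckets partition the deduplicated input.
#'
#' @param terms Character vector of descriptor strings (duplicates dropped).
#' @param vocab A `mesh_vocabulary` supplying tree numbers.
#' @param methodology_branches,health_branches Tree-number prefixes.
#' @return List with components `methodology`, `health`, `unassigned`.
#' @export
categorize_mesh <- function(terms, vocab,
                            methodology_branches = c("E", "L", "V"),
                            health_branches = c("C", "F", "G")) {
  terms <- unique(terms)
  buckets <- list(methodology = character(), health = character(),
                  unassigned = character())
  starts_with_any <- function(tn, prefixes) {
    vapply(tn, function(t) any(startsWith(t, prefixes)), logical(1))
  }
  for (term in terms) {
    canon <- mesh_lookup(vocab, term)
    if (is.na(canon)) {
      warning("MeSH term not in vocabulary: ", term, call. = FALSE)
      buckets$unassigned <- c(buckets$unassigned, term)
      next
    }
    tn <- mesh_tree_numbers(vocab, canon)
    if (length(tn) > 0L && any(starts_with_any(tn, health_branches))) {
      buckets$health <- c(buckets$health, term)
    } else if (length(tn) > 0L && all(starts_with_any(tn, methodology_branches))) {
      buckets$methodology <- c(buckets$methodology, term)
    } else {
      buckets$unassigned <- c(buckets$unassigned, term)
    }
  }
  buckets
}

#' Scan a token sequence for MeSH terms
#'
#' Longest-match left-to-right phrase scan: at each position the longest
#' phrase (up to the vocabulary's longest entry) matching a descriptor or
#' entry term is consumed. Used by the novel-term counter to restrict
#' candidate terms to recognized biomedical concepts.
#'
#' @param tokens Character vector of (already normalized or raw) tokens.
#' @param vocab A `mesh_vocabulary`.
#' @return Character vector of matched phrases (space-joined normalized
#'   tokens), in order of occurrence, possibly with duplicates.
#' @export
mesh_match_terms <- function(tokens, vocab) {
  toks <- vapply(tokens, normalize_mesh_term, character(1), USE.NAMES = FALSE)
  toks <- toks[nzchar(toks)]
  n <- length(toks)
  out <- character()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(vocab$max_phrase_len, n - i + 1L), 1L)) {
      phrase <- paste(toks[i:(i + len - 1L)], collapse = " ")
      if (exists(phrase, envir = vocab$term_map, inherits = FALSE)) {
        out <- c(out, phrase)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out
}

#' Serialize a MeSH vocabulary to descriptor XML
#'
#' Writes the subset of the `desc*.xml` dialect that [load_mesh_vocabulary()]
#' reads; used by the synthetic-corpus generator to emit fixtures in the
#' real input format.
#'
#' @param vocab A `mesh_vocabulary`.
#' @param path Output file path, or `NULL` to return the document.
#' @return Invisibly, the `xml_document`.
#' @export
write_mesh_xml <- function(vocab, path = NULL) {
  doc <- xml2::xml_new_root("DescriptorRecordSet")
  for (d in vocab$descriptors) {
    rec <- xml2::xml_add_child(doc, "DescriptorRecord")
    dn <- xml2::xml_add_child(rec, "DescriptorName")
    xml2::xml_add_child(dn, "String", d)
    tnl <- xml2::xml_add_child(rec, "TreeNumberList")
    for (tn in vocab$tree_numbers[[d]]) xml2::xml_add_child(tnl, "TreeNumber", tn)
    cl <- xml2::xml_add_child(rec, "ConceptList")
    con <- xml2::xml_add_child(cl, "Concept")
    tl <- xml2::xml_add_child(con, "TermList")
    for (t in unique(c(d, vocab$entry_terms[[d]]))) {
      term <- xml2::xml_add_child(tl, "Term")
      xml2::xml_add_child(term, "String", t)
    }
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}
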
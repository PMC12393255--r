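#' Construct a publication record
#'
#' One PubMed article: identifier, title, abstract (possibly empty), ordered
#' author list, MeSH headings with major-topic flags, and publication year.
#'
#' @param pmid Non-empty PubMed identifier string.
#' @param title Article title.
#' @param abstract Abstract text; `""` when the article has none.
#' @param authors Data frame with columns `surname`, `given`, `affiliation`
#'   (character), one row per author in byline order. Must have at least one
#'   row.
#' @param mesh_headings Data frame with columns `descriptor` (character) and
#'   `major` (logical), possibly zero rows.
#' @param pub_year Integer 4-digit publication year, or `NA` when PubMed
#'   supplies none.
#' @return An object of class `publication_record`.
#' @export
publication_record <- function(pmid, title, abstract = "", authors,
                               mesh_headings = empty_mesh_headings(),
                               pub_year = NA_integer_) {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid))
  authors <- tibble::as_tibble(authors)
  if (nrow(authors) < 1L) {
    stop("a publication record needs at least one author", call. = FALSE)
  }
  for (col in c("surname", "given", "affiliation")) {
    if (!col %in% names(authors)) authors[[col]] <- NA_character_
  }
  mesh_headings <- tibble::as_tibble(mesh_headings)
  pub_year <- as.integer(pub_year)
  if (!is.na(pub_year) && (pub_year < 1000L || pub_year > 9999L)) {
    stop("pub_year must be a 4-digit year or NA, got ", pub_year, call. = FALSE)
  }
  structure(
    list(
      pmid = pmid,
      title = as.character(title),
      abstract = if (is.na(abstract)) "" else as.character(abstract),
      authors = authors[c("surname", "given", "affiliation")],
      mesh_headings = mesh_headings,
      pub_year = pub_year
    ),
    class = "publication_record"
  )
}

empty_mesh_headings <- function() {
  tibble::tibble(descriptor = character(), major = logical())
}

#' @export
print.publication_record <- function(x, ...) {
  cat("<publication_record> PMID", x$pmid, "(", x$pub_year, ")\n")
  cat("  ", x$title, "\n", sep = "")
  cat("  ", nrow(x$authors), " authors, ", nrow(x$mesh_headings),
      " MeSH headings, abstract ", nchar(x$abstract), " chars\n", sep = "")
  invisible(x)
}

#' Construct a researcher dossier
#'
#' A researcher together with their (possibly unfiltered) publications and an
#' optional self-written research-interest profile. Profiles are absent for
#' most researchers in realistic corpora; such dossiers still enter profile
#' generation but are excluded from reference-based evaluation.
#'
#' @param name Researcher name, `"Given Surname"` or `"Surname, Given"`.
#' @param affiliation Free-text affiliation used for coarse disambiguation.
#' @param publications List of [publication_record()] objects.
#' @param human_profile Self-written profile text, or `NULL` when absent.
#' @return An object of class `researcher_dossier`.
#' @export
researcher_dossier <- function(name, affiliation = "", publications = list(),
                               human_profile = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ok <- vapply(publications, inherits, logical(1), "publication_record")
  if (!all(ok)) stop("publications must all be publication_record objects", call. = FALSE)
  pmids <- vapply(publications, function(p) p$pmid, character(1))
  if (anyDuplicated(pmids)) {
    stop("duplicate PMIDs within a dossier: ",
         paste(unique(pmids[duplicated(pmids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, affiliation = affiliation,
         publications = publications, human_profile = human_profile),
    class = "researcher_dossier"
  )
}

#' @export
print.researcher_dossier <- function(x, ...) {
  cat("<researcher_dossier>", x$name, "-", length(x$publications),
      "publications,", if (is.null(x$human_profile)) "no" else "has",
      "human profile\n")
  invisible(x)
}

#' Parse PubMed efetch XML into publication records
#'
#' Reads the `PubmedArticleSet` dialect returned by the NCBI E-utilities
#' `efetch` endpoint. A missing abstract yields an empty string, never a
#' failure; MeSH descriptor names are captured verbatim. Articles without a
#' PMID are skipped with a warning.
#'
#' @param source Path, URL, raw vector or literal XML string.
#' @return List of [publication_record()] objects (possibly empty).
#' @export
parse_pubmed_xml <- function(source) {
  doc <- xml2::read_xml(source)
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  records <- list()
  for (node in articles) {
    pmid <- xml2::xml_text(xml2::xml_find_first(node, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("skipping article without PMID", call. = FALSE)
      next
    }
    art <- xml2::xml_find_first(node, ".//Article")
    title <- xml2::xml_text(xml2::xml_find_first(art, "./ArticleTitle"))
    if (is.na(title)) title <- ""
    abs_nodes <- xml2::xml_find_all(art, "./Abstract/AbstractText")
    abstract <- if (length(abs_nodes) == 0L) "" else
      paste(xml2::xml_text(abs_nodes), collapse = " ")
    auth_nodes <- xml2::xml_find_all(art, "./AuthorList/Author")
    authors <- tibble::tibble(
      surname = vapply(auth_nodes, function(a)
        xml2::xml_text(xml2::xml_find_first(a, "./LastName")), character(1)),
      given = vapply(auth_nodes, function(a)
        xml2::xml_text(xml2::xml_find_first(a, "./ForeName")), character(1)),
      affiliation = vapply(auth_nodes, function(a)
        xml2::xml_text(xml2::xml_find_first(a, "./AffiliationInfo/Affiliation")),
        character(1))
    )
    mesh_nodes <- xml2::xml_find_all(node, ".//MeshHeadingList/MeshHeading")
    mesh <- tibble::tibble(
      descriptor = vapply(mesh_nodes, function(m)
        xml2::xml_text(xml2::xml_find_first(m, "./DescriptorName")), character(1)),
      major = vapply(mesh_nodes, function(m)
        identical(xml2::xml_attr(xml2::xml_find_first(m, "./DescriptorName"),
                                 "MajorTopicYN"), "Y"), logical(1))
    )
    year_node <- xml2::xml_find_first(
      node, ".//Article/Journal/JournalIssue/PubDate/Year")
    year <- xml2::xml_text(year_node)
    if (is.na(year)) {
      # MedlineDate fallback, e.g. "2019 Jan-Feb"
      md <- xml2::xml_text(xml2::xml_find_first(
        node, ".//Article/Journal/JournalIssue/PubDate/MedlineDate"))
      year <- if (!is.na(md)) stringr::str_extract(md, "\\d{4}") else NA_character_
    }
    records[[length(records) + 1L]] <- publication_record(
      pmid = pmid, title = title, abstract = abstract,
      authors = authors, mesh_headings = mesh,
      pub_year = suppressWarnings(as.integer(year))
    )
  }
  records
}

#' Serialize publication records to PubMed efetch XML
#'
#' Writes the subset of the `PubmedArticleSet` dialect that
#' [parse_pubmed_xml()] reads, so that parse - serialize - parse round-trips
#' preserve PMID, year, author order and MeSH descriptor names. Also used by
#' the synthetic-corpus generator to emit fixtures in the real input format.
#'
#' @param records List of [publication_record()] objects.
#' @param path Output file path, or `NULL` to return the XML document.
#' @return Invisibly, the `xml_document`.
#' @export
write_pubmed_xml <- function(records, path = NULL) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (rec in records) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", rec$pmid)
    a <- xml2::xml_add_child(cit, "Article")
    j <- xml2::xml_add_child(a, "Journal")
    ji <- xml2::xml_add_child(j, "JournalIssue")
    pd <- xml2::xml_add_child(ji, "PubDate")
    if (!is.na(rec$pub_year)) xml2::xml_add_child(pd, "Year", as.character(rec$pub_year))
    xml2::xml_add_child(a, "ArticleTitle", rec$title)
    if (nzchar(rec$abstract)) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", rec$abstract)
    }
    al <- xml2::xml_add_child(a, "AuthorList")
    for (i in seq_len(nrow(rec$authors))) {
      au <- xml2::xml_add_child(al, "Author")
      xml2::xml_add_child(au, "LastName", rec$authors$surname[i])
      xml2::xml_add_child(au, "ForeName", rec$authors$given[i])
      if (!is.na(rec$authors$affiliation[i]) && nzchar(rec$authors$affiliation[i])) {
        ai <- xml2::xml_add_child(au, "AffiliationInfo")
        xml2::xml_add_child(ai, "Affiliation", rec$authors$affiliation[i])
      }
    }
    if (nrow(rec$mesh_headings) > 0L) {
      ml <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (i in seq_len(nrow(rec$mesh_headings))) {
        mh <- xml2::xml_add_child(ml, "MeshHeading")
        dn <- xml2::xml_add_child(mh, "DescriptorName", rec$mesh_headings$descriptor[i])
        xml2::xml_set_attr(dn, "MajorTopicYN",
                           if (isTRUE(rec$mesh_headings$major[i])) "Y" else "N")
      }
    }
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}

#' Parse MEDLINE flat-text format
#'
#' Minimal reader for the tagged MEDLINE text format (`PMID-`, `TI-`, `AB-`,
#' `FAU-`, `MH-`, `DP-` fields with 6-character tag columns and continuation
#' lines). Affiliations are not carried by the per-author fields read here.
#'
#' @param source Path to a MEDLINE text file, or a character vector of lines.
#' @return List of [publication_record()] objects.
#' @export
parse_medline <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  # fold continuation lines (6 leading spaces) into the preceding field
  folded <- character()
  for (ln in lines) {
    if (grepl("^ {6}", ln) && length(folded) > 0L) {
      folded[length(folded)] <- paste(folded[length(folded)], trimws(ln))
    } else folded <- c(folded, ln)
  }
  blocks <- split(folded, cumsum(grepl("^PMID-", folded)))
  blocks <- blocks[names(blocks) != "0"]
  lapply(blocks, function(b) {
    field <- function(tag) {
      hits <- b[grepl(paste0("^", tag, " *- "), b)]
      sub(paste0("^", tag, " *- "), "", hits)
    }
    fau <- field("FAU")   # "Surname, Given"
    surname <- sub(",.*$", "", fau)
    given <- trimws(sub("^[^,]*,", "", fau))
    mh <- sub("^\\*", "", field("MH"))
    publication_record(
      pmid = field("PMID")[1],
      title = paste(field("TI"), collapse = " "),
      abstract = paste(field("AB"), collapse = " "),
      authors = tibble::tibble(surname = surname, given = given,
                               affiliation = NA_character_),
      mesh_headings = tibble::tibble(descriptor = mh,
                                     major = startsWith(field("MH"), "*")),
      pub_year = suppressWarnings(as.integer(stringr::str_extract(
        field("DP")[1], "\\d{4}")))
    )
  })
}

split_name <- function(name) {
  if (grepl(",", name)) {
    parts <- strsplit(name, ",")[[1]]
    list(surname = trimws(parts[1]), given = trimws(paste(parts[-1], collapse = " ")))
  } else {
    toks <- strsplit(trimws(name), "\\s+")[[1]]
    list(surname = toks[length(toks)],
         given = if (length(toks) > 1L) paste(toks[-length(toks)], collapse = " ") else "")
  }
}

#' Locate a researcher in an author byline
#'
#' Matching is by case-folded surname plus first given-name initial (when the
#' researcher name supplies one). When more than one author matches, the
#' dossier affiliation can be used as a substring tie-breaker by the caller;
#' here the first match is taken. The first-author block is authors 1-3; the
#' last-author block is the final three. On short bylines where the blocks
#' overlap, the first block takes precedence.
#'
#' @param record A [publication_record()].
#' @param researcher_name Name as `"Given Surname"` or `"Surname, Given"`.
#' @param affiliation Optional affiliation substring used only to break ties
#'   between multiple byline matches.
#' @return One of `"first_block"`, `"last_block"`, `"middle"`, `"absent"`.
#' @export
author_position <- function(record, researcher_name, affiliation = NULL) {
  nm <- split_name(researcher_name)
  surnames <- tolower(record$authors$surname)
  hit <- which(surnames == tolower(nm$surname))
  if (length(hit) > 1L && nzchar(nm$given)) {
    init <- toupper(substr(nm$given, 1, 1))
    given_init <- toupper(substr(record$authors$given[hit], 1, 1))
    refined <- hit[!is.na(given_init) & given_init == init]
    if (length(refined) > 0L) hit <- refined
  } else if (length(hit) == 1L && nzchar(nm$given)) {
    gi <- record$authors$given[hit]
    if (!is.na(gi) && nzchar(gi) &&
        toupper(substr(gi, 1, 1)) != toupper(substr(nm$given, 1, 1))) {
      hit <- integer()
    }
  }
  if (length(hit) > 1L && !is.null(affiliation) && nzchar(affiliation)) {
    aff <- tolower(record$authors$affiliation[hit])
    refined <- hit[!is.na(aff) & grepl(tolower(affiliation), aff, fixed = TRUE)]
    if (length(refined) > 0L) hit <- refined
  }
  if (length(hit) == 0L) return("absent")
  idx <- hit[1]
  n <- nrow(record$authors)
  if (idx <= 3L) return("first_block")
  if (idx > n - 3L) return("last_block")
  "middle"
}

#' Filter a dossier's publications by recency and authorship position
#'
#' Retains publications inside a closed calendar-year window ending at
#' `reference_year` on which the researcher sits in a contributing authorship
#' position. The default rule keeps first-block or last-block authors; the
#' stricter rule keeps first-block or sole senior (final) author. Records
#' without a publication year are dropped with a warning. The input dossier
#' is not modified and publication order is preserved, so filtering is
#' idempotent.
#'
#' @param dossier A [researcher_dossier()].
#' @param reference_year Final year of the window (required; no clock access).
#' @param window_years Window width in calendar years, default 10.
#' @param author_rule `"first3last3"` (default) or `"first3senior"`.
#' @return A new `researcher_dossier` with the retained publications.
#' @export
filter_publications <- function(dossier, reference_year, window_years = 10L,
                                author_rule = c("first3last3", "first3senior")) {
  author_rule <- match.arg(author_rule)
  window_years <- as.integer(window_years)
  if (is.na(window_years) || window_years < 1L) {
    stop("window_years must be a positive integer", call. = FALSE)
  }
  reference_year <- as.integer(reference_year)
  stopifnot(!is.na(reference_year))
  min_year <- reference_year - window_years + 1L
  keep <- vapply(dossier$publications, function(p) {
    if (is.na(p$pub_year)) {
      warning("publication ", p$pmid, " has no year; excluded", call. = FALSE)
      return(FALSE)
    }
    if (p$pub_year < min_year || p$pub_year > reference_year) return(FALSE)
    pos <- author_position(p, dossier$name, dossier$affiliation)
    if (author_rule == "first3last3") {
      pos %in% c("first_block", "last_block")
    } else {
      pos == "first_block" ||
        (pos == "last_block" &&
           author_matches_senior(p, dossier$name))
    }
  }, logical(1))
  researcher_dossier(
    name = dossier$name, affiliation = dossier$affiliation,
    publications = dossier$publications[keep],
    human_profile = dossier$human_profile
  )
}

# senior author = final byline position
author_matches_senior <- function(record, researcher_name) {
  nm <- split_name(researcher_name)
  n <- nrow(record$authors)
  last <- record$authors[n, ]
  if (tolower(last$surname) != tolower(nm$surname)) return(FALSE)
  if (!nzchar(nm$given) || is.na(last$given) || !nzchar(last$given)) return(TRUE)
  toupper(substr(last$given, 1, 1)) == toupper(substr(nm$given, 1, 1))
}

#' Serialize dossiers to and from JSON
#'
#' @param dossiers List of [researcher_dossier()] objects.
#' @param path Output path (`dossiers_to_json`) or input path/JSON string
#'   (`dossiers_from_json`).
#' @return `dossiers_to_json` invisibly returns the JSON string;
#'   `dossiers_from_json` returns a list of dossiers.
#' @export
dossiers_to_json <- function(dossiers, path = NULL) {
  payload <- lapply(dossiers, function(d) {
    list(
      name = d$name, affiliation = d$affiliation,
      human_profile = d$human_profile,
      publications = lapply(d$publications, function(p) {
        list(pmid = p$pmid, title = p$title, abstract = p$abstract,
             pub_year = p$pub_year, authors = p$authors,
             mesh_headings = p$mesh_headings)
      })
    )
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}

#' @rdname dossiers_to_json
#' @export
dossiers_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(d) {
    pubs <- lapply(d$publications, function(p) {
      publication_record(
        pmid = p$pmid, title = p$title, abstract = p$abstract %||% "",
        authors = tibble::tibble(
          surname = vapply(p$authors, function(a) a$surname %||% NA_character_, character(1)),
          given = vapply(p$authors, function(a) a$given %||% NA_character_, character(1)),
          affiliation = vapply(p$authors, function(a) a$affiliation %||% NA_character_, character(1))
        ),
        mesh_headings = tibble::tibble(
          descriptor = vapply(p$mesh_headings, function(m) m$descriptor, character(1)),
          major = vapply(p$mesh_headings, function(m) isTRUE(m$major), logical(1))
        ),
        pub_year = p$pub_year %||% NA_integer_
      )
    })
    researcher_dossier(name = d$name, affiliation = d$affiliation %||% "",
                       publications = pubs, human_profile = d$human_profile)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
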
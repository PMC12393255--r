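#' Assemble a pipeline run configuration
#'
#' A fully serializable description of one evaluation run: seeds, filter
#' thresholds, strategy and metric toggles, and backend selection. A run
#' re-executed from its saved configuration with a deterministic backend
#' reproduces its outputs byte for byte.
#'
#' @param seed Global seed.
#' @param reference_year,window_years Publication filter window.
#' @param author_rule Authorship rule for [filter_publications()].
#' @param n_topics LDA topic count for the stability analysis.
#' @param chunk_topics Topic count for abstract-strategy grouping.
#' @param epsilon KL smoothing mass.
#' @param alpha Significance level for paired t-tests.
#' @param backend Backend selector: `"extractive"`, `"echo"`, `"identity"`,
#'   `"shuffle"`.
#' @param strategies Character subset of `c("mesh", "abstract", "paraphrase")`.
#' @param kl_direction Passed to [profile_kl()].
#' @param holm Apply Holm correction across the per-metric t-tests.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, reference_year = 2024L, window_years = 10L,
                       author_rule = "first3last3", n_topics = 30L,
                       chunk_topics = 5L, epsilon = 1e-9, alpha = 0.05,
                       backend = "extractive",
                       strategies = c("mesh", "abstract", "paraphrase"),
                       kl_direction = "human_vs_machine", holm = FALSE) {
  cfg <- list(seed = as.integer(seed), reference_year = as.integer(reference_year),
              window_years = as.integer(window_years), author_rule = author_rule,
              n_topics = as.integer(n_topics), chunk_topics = as.integer(chunk_topics),
              epsilon = epsilon, alpha = alpha, backend = backend,
              strategies = strategies, kl_direction = kl_direction,
              holm = isTRUE(holm))
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' The JSON serialization is canonical (fixed field order, no rounding), so
#' save - load - save round-trips are byte-identical.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `save_config` invisibly returns the path; `load_config` returns
#'   the `run_config`.
#' @export
save_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

resolve_backend <- function(cfg) {
  switch(cfg$backend,
         extractive = backend_extractive(),
         echo = backend_echo(),
         identity = backend_identity(),
         shuffle = backend_shuffle(seed = cfg$seed),
         stop("unknown backend: ", cfg$backend, call. = FALSE))
}

config_hash <- function(cfg) {
  # cheap order-stable fingerprint; not cryptographic
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483563
  sprintf("%08x", h)
}

#' Run the full profiling-and-evaluation pipeline
#'
#' Filters every dossier, generates profiles with the enabled strategies
#' over the configured backend, evaluates machine profiles against
#' human-written ones with the lexical, vocabulary-shift, embedding and
#' syntactic metric families, runs the topic-stability analysis, and
#' attaches paired t-tests between systems. Researchers without a human
#' profile are kept for generation but excluded from reference-based
#' evaluation; every exclusion is tallied in the report. The report embeds
#' the configuration hash and seed (no wall-clock state), so identical runs
#' produce identical bundles.
#'
#' @param dossiers List of [researcher_dossier()] objects.
#' @param mesh_vocab A `mesh_vocabulary`.
#' @param cfg A [run_config()].
#' @param parser Parser contract for the syntactic family; default
#'   [parser_flat()] (degenerate; supply CoNLL-U-backed parses for real
#'   analyses).
#' @return List of class `profile_report`; see Details.
#' @details The bundle contains `profiles` (per-researcher generated
#'   texts), `lexical` (per-system score tables and means), `kl`
#'   (vocabulary-shift divergences with mean and population variance),
#'   `novel_terms`, `bertscore`, `syntactic`, `topics` (diversity records
#'   and year-by-topic table), `tests` (paired t-tests with significance
#'   labels), `exclusions`, and `provenance`.
#' @export
run_pipeline <- function(dossiers, mesh_vocab, cfg = run_config(),
                         parser = parser_flat()) {
  backend <- resolve_backend(cfg)
  exclusions <- list()
  filtered <- lapply(dossiers, filter_publications,
                     reference_year = cfg$reference_year,
                     window_years = cfg$window_years,
                     author_rule = cfg$author_rule)
  usable <- vapply(filtered, function(d) length(d$publications) > 0L, logical(1))
  if (any(!usable)) {
    exclusions$no_publications_after_filter <-
      vapply(filtered[!usable], function(d) d$name, character(1))
  }
  filtered <- filtered[usable]

  profiles <- purrr::map(filtered, function(d) {
    out <- list(researcher = d$name, human = d$human_profile)
    if ("mesh" %in% cfg$strategies) {
      out$mesh <- tryCatch(
        as.character(generate_profile_mesh(d, backend, mesh_vocab = mesh_vocab)),
        error = function(e) NA_character_)
    }
    if ("abstract" %in% cfg$strategies) {
      out$abstract <- tryCatch(
        as.character(generate_profile_abstract(
          d, backend, n_topics = cfg$chunk_topics, seed = cfg$seed)),
        error = function(e) NA_character_)
    }
    if ("paraphrase" %in% cfg$strategies && !is.null(d$human_profile)) {
      out$paraphrase <- as.character(
        paraphrase_profile(d$human_profile, backend))
    }
    out
  })

  with_ref <- purrr::keep(profiles, function(p) !is.null(p$human))
  if (length(with_ref) < length(profiles)) {
    exclusions$no_human_profile <- vapply(
      purrr::discard(profiles, function(p) !is.null(p$human)),
      function(p) p$researcher, character(1))
  }

  systems <- intersect(cfg$strategies, c("mesh", "abstract", "paraphrase"))
  evaluated <- length(with_ref) > 0L

  lexical <- NULL; kl <- NULL; novel <- NULL; bert <- NULL; syntactic <- NULL
  tests <- NULL
  if (evaluated) {
    ids <- vapply(with_ref, function(p) p$researcher, character(1))
    humans <- vapply(with_ref, function(p) p$human, character(1))
    sys_texts <- lapply(systems, function(s)
      vapply(with_ref, function(p) p[[s]] %||% NA_character_, character(1)))
    names(sys_texts) <- systems

    lexical <- purrr::map(sys_texts, function(texts) {
      ok <- !is.na(texts)
      score_pairs(texts[ok], humans[ok], ids = ids[ok])
    })
    kl <- purrr::map(sys_texts, function(texts) {
      ok <- !is.na(texts)
      profile_kl_batch(humans[ok], texts[ok], ids = ids[ok],
                       epsilon = cfg$epsilon, direction = cfg$kl_direction)
    })
    machine_only <- sys_texts[intersect(systems, c("mesh", "abstract"))]
    novel <- purrr::map(seq_along(ids), function(i) {
      machines <- stats::na.omit(vapply(machine_only, `[`, character(1), i))
      res <- novel_term_count(humans[i], machines, mesh_vocab = mesh_vocab)
      tibble::tibble(id = ids[i], novel_count = res$count,
                     novel_terms = paste(res$terms, collapse = "; "))
    })
    novel <- dplyr::bind_rows(novel)
    embedder <- random_projection_embedder(seed = cfg$seed)
    bert <- purrr::map(sys_texts, function(texts) {
      ok <- !is.na(texts)
      rows <- purrr::map2(texts[ok], humans[ok], function(cand, ref) {
        b <- bert_score(tokenize_words(cand), tokenize_words(ref), embedder)
        tibble::tibble(precision = b[["precision"]], recall = b[["recall"]],
                       f1 = b[["f1"]])
      })
      scores <- dplyr::bind_cols(tibble::tibble(id = ids[ok]),
                                 dplyr::bind_rows(rows))
      list(scores = scores, means = colMeans(scores[-1]))
    })
    syn_profiles <- purrr::map(c(list(human = humans), sys_texts), function(texts) {
      ok <- !is.na(texts)
      rows <- purrr::map(which(ok), function(i) {
        sp <- tryCatch(syntactic_profile(texts[i], parser),
                       error = function(e) NULL)
        if (is.null(sp)) return(NULL)
        tibble::tibble(id = ids[i], max_dep_depth = sp$max_dep_depth,
                       complexity = sp$syntactic_complexity,
                       ambiguity = sp$syntactic_ambiguity)
      })
      dplyr::bind_rows(rows)
    })
    syntactic <- syn_profiles

    # paired t-tests between systems on BLEU and BERTScore F1
    tests <- list()
    pair_names <- utils::combn(systems, 2, simplify = FALSE)
    if (length(systems) >= 2L) {
      for (pr in pair_names) {
        a <- lexical[[pr[1]]]$scores
        b <- lexical[[pr[2]]]$scores
        shared <- intersect(a$id, b$id)
        if (length(shared) >= 2L) {
          tests[[paste0("bleu:", pr[1], "_vs_", pr[2])]] <-
            paired_t_test(a$bleu[match(shared, a$id)],
                          b$bleu[match(shared, b$id)], alpha = cfg$alpha)
          fa <- bert[[pr[1]]]$scores; fb <- bert[[pr[2]]]$scores
          tests[[paste0("bert_f1:", pr[1], "_vs_", pr[2])]] <-
            paired_t_test(fa$f1[match(shared, fa$id)],
                          fb$f1[match(shared, fb$id)], alpha = cfg$alpha)
        }
      }
      if (cfg$holm && length(tests) > 0L) {
        ps <- vapply(tests, function(t) t$p %||% NA_real_, numeric(1))
        adj <- stats::p.adjust(ps, method = "holm")
        for (i in seq_along(tests)) {
          tests[[i]]$p_holm <- adj[i]
          if (!is.na(adj[i])) {
            tests[[i]]$significant <- adj[i] < cfg$alpha
            tests[[i]]$label <- significance_legend(adj[i])
          }
        }
      }
    }
  }

  # topic-stability analysis over all abstracts in the filtered corpus
  all_abstracts <- unlist(lapply(filtered, function(d)
    vapply(d$publications, function(p) p$abstract, character(1))))
  all_abstracts <- all_abstracts[nzchar(all_abstracts)]
  topics_block <- NULL
  if (length(all_abstracts) > 0L) {
    k <- min(cfg$n_topics, length(all_abstracts))
    model <- suppressWarnings(fit_lda(as.list(all_abstracts), n_topics = k,
                                      seed = cfg$seed))
    diversity <- dplyr::bind_rows(purrr::map(filtered, function(d) {
      tryCatch(diversity_score(model, d$publications, id = d$name),
               error = function(e) NULL)
    }))
    topics_block <- list(model = model, diversity = diversity,
                         year_table = topic_year_table(model, filtered))
  }

  structure(list(
    profiles = profiles, lexical = lexical, kl = kl, novel_terms = novel,
    bertscore = bert, syntactic = syntactic, topics = topics_block,
    tests = tests,
    exclusions = exclusions,
    evaluation_empty = !evaluated,
    provenance = list(config = unclass(cfg), config_hash = config_hash(cfg),
                      backend = backend$name,
                      n_researchers = length(filtered),
                      n_evaluated = if (evaluated) length(with_ref) else 0L)
  ), class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat("<profile_report>", x$provenance$n_researchers, "researchers,",
      x$provenance$n_evaluated, "evaluated ( backend",
      x$provenance$backend, ", config", x$provenance$config_hash, ")\n")
  if (x$evaluation_empty) {
    cat("  NOTE: no researcher had a human-written profile;",
        "evaluation section is empty\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Per-researcher metric tables go to CSV, the consolidated summary (means,
#' tests, provenance, exclusions) to JSON. Output is deterministic given a
#' deterministic backend: no timestamps are embedded.
#'
#' @param report A `profile_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE)
  if (!is.null(report$lexical)) {
    for (s in names(report$lexical)) {
      wcsv(report$lexical[[s]]$scores, paste0("lexical_", s, ".csv"))
      wcsv(report$bertscore[[s]]$scores, paste0("bertscore_", s, ".csv"))
      wcsv(report$kl[[s]]$scores, paste0("kl_", s, ".csv"))
    }
    wcsv(report$novel_terms, "novel_terms.csv")
    for (s in names(report$syntactic)) {
      wcsv(report$syntactic[[s]], paste0("syntactic_", s, ".csv"))
    }
  }
  if (!is.null(report$topics)) {
    wcsv(report$topics$diversity, "diversity.csv")
    wcsv(report$topics$year_table, "topic_year.csv")
  }
  summary <- list(
    provenance = report$provenance,
    exclusions = report$exclusions,
    evaluation_empty = report$evaluation_empty,
    means = if (!is.null(report$lexical)) list(
      lexical = lapply(report$lexical, function(x) as.list(x$means)),
      bertscore = lapply(report$bertscore, function(x) as.list(x$means)),
      kl = lapply(report$kl, function(x) list(mean = x$mean,
                                              variance = x$variance)),
      novel_terms_total = sum(report$novel_terms$novel_count)
    ),
    tests = lapply(report$tests, function(t)
      t[c("t", "p", "significant", "label", "degenerate")])
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             file.path(dir, "summary.json"))
  invisible(dir)
}
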
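#' Construct a text-generation backend
#'
#' A backend is the pluggable contract behind both profile-generation
#' strategies: a `generate(prompt, max_output_tokens)` function plus a
#' declared context limit (in tokens) and a determinism flag. Remote-LLM
#' adapters implement the same contract; the packaged backends below are
#' deterministic and run offline, so the whole pipeline is testable without
#' a model.
#'
#' @param generate Function `(prompt, max_output_tokens) -> character`.
#' @param context_limit Maximum prompt size in tokens the backend accepts.
#' @param deterministic Does the same prompt always give the same output?
#' @param name Short backend name used in provenance logs.
#' @param tokenizer Optional `function(text) -> integer` token counter; when
#'   absent, budgets are checked with whitespace tokens times an inflation
#'   factor.
#' @return Object of class `generation_backend`.
#' @export
generation_backend <- function(generate, context_limit = 128000L,
                               deterministic = FALSE, name = "backend",
                               tokenizer = NULL) {
  stopifnot(is.function(generate))
  structure(list(generate = generate, context_limit = as.integer(context_limit),
                 deterministic = isTRUE(deterministic), name = name,
                 tokenizer = tokenizer),
            class = "generation_backend")
}

#' @export
print.generation_backend <- function(x, ...) {
  cat("<generation_backend>", x$name, "- context", x$context_limit, "tokens,",
      if (x$deterministic) "deterministic" else "stochastic", "\n")
  invisible(x)
}

#' Count tokens for prompt-budget checks
#'
#' Uses the backend's tokenizer when it declares one; otherwise whitespace
#' tokens times a configurable inflation factor approximating subword
#' tokenization.
#'
#' @param text Character scalar.
#' @param backend Optional `generation_backend`.
#' @param inflation Multiplier on the whitespace-token count, default 1.3.
#' @return Integer (ceiling) token estimate.
#' @export
count_tokens <- function(text, backend = NULL, inflation = 1.3) {
  if (!is.null(backend) && !is.null(backend$tokenizer)) {
    return(as.integer(backend$tokenizer(text)))
  }
  n_ws <- length(strsplit(trimws(text), "\\s+")[[1]])
  as.integer(ceiling(n_ws * inflation))
}

# material marker: deterministic backends that transform only the
# researcher's material (not the instruction scaffold) locate it after this
# line, mirroring how an instruction-following model treats the input slot
input_marker <- function() "Input:\n"

extract_input <- function(prompt) {
  marker <- input_marker()
  pos <- gregexpr(marker, prompt, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return(prompt)
  start <- pos[length(pos)] + nchar(marker)
  substr(prompt, start, nchar(prompt))
}

#' Packaged deterministic backends
#'
#' * `backend_extractive()` - the default offline summarizer: splits the
#'   material into sentences, ranks them by summed TF-IDF of their content
#'   words (each sentence a document of the within-material corpus), keeps
#'   the top `top_k` (ties to the earlier sentence) and emits them in
#'   original order. Deterministic, so generation is reproducible
#'   bit-for-bit.
#' * `backend_echo()` - returns the full rendered prompt; used to test that
#'   prompts contain what they should.
#' * `backend_identity()` - returns the material verbatim; the paraphrase
#'   strategy's fixed point.
#' * `backend_shuffle(seed)` - returns the material's tokens in seeded
#'   random order (a degenerate "paraphrase" preserving the token multiset).
#'
#' @param top_k Number of sentences the extractive backend keeps.
#' @param context_limit Declared context limit in tokens.
#' @param seed Seed for the shuffle backend.
#' @return A [generation_backend()].
#' @export
backend_extractive <- function(top_k = 5L, context_limit = 128000L) {
  generation_backend(
    generate = function(prompt, max_output_tokens = NULL) {
      material <- extract_input(prompt)
      sents <- strsplit(material, "(?<=[.!?])\\s+|\n+", perl = TRUE)[[1]]
      sents <- trimws(sents)
      sents <- sents[nzchar(sents)]
      if (length(sents) == 0L) return(trimws(material))
      if (length(sents) == 1L) return(sents)
      weights <- tfidf_weights(as.list(sents))
      score <- vapply(weights, sum, numeric(1))
      keep <- order(-score, seq_along(sents))[seq_len(min(top_k, length(sents)))]
      paste(sents[sort(keep)], collapse = " ")
    },
    context_limit = context_limit, deterministic = TRUE, name = "extractive"
  )
}

#' @rdname backend_extractive
#' @export
backend_echo <- function(context_limit = 128000L) {
  generation_backend(
    generate = function(prompt, max_output_tokens = NULL) prompt,
    context_limit = context_limit, deterministic = TRUE, name = "echo"
  )
}

#' @rdname backend_extractive
#' @export
backend_identity <- function(context_limit = 128000L) {
  generation_backend(
    generate = function(prompt, max_output_tokens = NULL) extract_input(prompt),
    context_limit = context_limit, deterministic = TRUE, name = "identity"
  )
}

#' @rdname backend_extractive
#' @export
backend_shuffle <- function(seed = 1L, context_limit = 128000L) {
  force(seed)
  generation_backend(
    generate = function(prompt, max_output_tokens = NULL) {
      toks <- strsplit(trimws(extract_input(prompt)), "\\s+")[[1]]
      set.seed(as.integer(seed))
      paste(sample(toks), collapse = " ")
    },
    context_limit = context_limit, deterministic = TRUE, name = "shuffle"
  )
}

#' Construct a one-shot prompt template
#'
#' A template holds an instruction and exactly one worked example (input
#' material plus the matching human-written profile). Rendering places the
#' target researcher's material in the input slot after the example.
#'
#' @param instruction Task instruction text.
#' @param example_input The example's material (MeSH buckets or abstracts).
#' @param example_output The example's human-written profile.
#' @return Object of class `prompt_template`.
#' @export
prompt_template <- function(instruction, example_input, example_output) {
  stopifnot(nzchar(instruction))
  structure(list(instruction = instruction, example_input = example_input,
                 example_output = example_output),
            class = "prompt_template")
}

#' Read a prompt template from a sectioned plain-text file
#'
#' Template files carry three named sections introduced by `## instruction`,
#' `## example_input` and `## example_output` header lines; everything under
#' a header up to the next one is that section's text. Editable copies ship
#' under `inst/templates/`.
#'
#' @param path Template file path.
#' @return A [prompt_template()].
#' @export
read_prompt_template <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^## ", lines)
  if (length(headers) == 0L) stop("no '## section' headers in template", call. = FALSE)
  sections <- list()
  for (i in seq_along(headers)) {
    name <- trimws(sub("^## ", "", lines[headers[i]]))
    end <- if (i < length(headers)) headers[i + 1L] - 1L else length(lines)
    body <- lines[seq(headers[i] + 1L, end)]
    sections[[name]] <- trimws(paste(body, collapse = "\n"))
  }
  prompt_template(sections$instruction %||% "",
                  sections$example_input %||% "",
                  sections$example_output %||% "")
}

#' Render a one-shot prompt
#'
#' @param template A [prompt_template()].
#' @param input The target researcher's material.
#' @return Character scalar prompt ending with the input slot.
#' @export
render_prompt <- function(template, input) {
  paste0(
    template$instruction, "\n\n",
    "Example input:\n", template$example_input, "\n",
    "Example output:\n", template$example_output, "\n\n",
    input_marker(), input
  )
}

default_template <- function(which = c("mesh", "abstract", "paraphrase", "combine")) {
  which <- match.arg(which)
  read_prompt_template(system.file("templates", paste0(which, ".txt"),
                                   package = "scholarprofiler"))
}

check_budget <- function(prompt, backend) {
  n <- count_tokens(prompt, backend)
  if (n > backend$context_limit) {
    stop("rendered prompt (", n, " tokens) exceeds the backend context limit (",
         backend$context_limit, ")", call. = FALSE)
  }
  invisible(n)
}

call_backend <- function(backend, prompt, max_output_tokens, log) {
  check_budget(prompt, backend)
  out <- tryCatch(backend$generate(prompt, max_output_tokens),
                  error = function(e) {
                    stop("backend '", backend$name, "' failed: ",
                         conditionMessage(e), "\n--- rendered prompt ---\n",
                         prompt, call. = FALSE)
                  })
  log[[length(log) + 1L]] <- list(backend = backend$name, prompt = prompt,
                                  response = out)
  list(out = out, log = log)
}

#' Generate a profile from MeSH keywords
#'
#' The keyword strategy: pools the dossier's unique MeSH headings, splits
#' them into methodology and health buckets by MeSH tree branch, and issues
#' a single one-shot prompt asking the backend to summarize each domain
#' separately. The backend output is returned verbatim with the prompt and
#' response attached as a provenance log.
#'
#' @param dossier A filtered [researcher_dossier()] with at least one MeSH
#'   heading across its publications.
#' @param backend A [generation_backend()].
#' @param template A [prompt_template()]; default the packaged MeSH template.
#' @param mesh_vocab A `mesh_vocabulary` for the methodology/health split.
#' @param max_output_tokens Passed to the backend.
#' @return Profile text with attribute `provenance` (list of prompt/response
#'   records).
#' @export
generate_profile_mesh <- function(dossier, backend,
                                  template = default_template("mesh"),
                                  mesh_vocab, max_output_tokens = 512L) {
  terms <- unique(unlist(lapply(dossier$publications,
                                function(p) p$mesh_headings$descriptor)))
  if (length(terms) == 0L) {
    stop("dossier has no MeSH headings; use the abstract strategy", call. = FALSE)
  }
  buckets <- categorize_mesh(terms, mesh_vocab)
  material <- paste0(
    "Methodology keywords: ",
    paste(c(buckets$methodology, buckets$unassigned), collapse = "; "), "\n",
    "Health-domain keywords: ", paste(buckets$health, collapse = "; "), "\n",
    "Summarize each domain separately."
  )
  prompt <- render_prompt(template, material)
  res <- call_backend(backend, prompt, max_output_tokens, list())
  structure(res$out, provenance = res$log)
}

#' Group publications by dominant LDA topic under a token budget
#'
#' Fits an LDA model on the dossier abstracts (all must be non-empty),
#' assigns each publication to its dominant topic, and greedily splits any
#' topic group whose abstracts exceed the token budget, preserving input
#' order. The union of the groups is exactly the input set.
#'
#' @param pubs List of [publication_record()] objects with non-empty
#'   abstracts.
#' @param n_topics Number of LDA topics; capped at the number of
#'   publications.
#' @param token_budget Maximum whitespace-inflated tokens per group; must
#'   accommodate every single abstract.
#' @param seed Integer seed for the LDA fit.
#' @return List of publication groups (lists of records).
#' @export
chunk_abstracts_by_topic <- function(pubs, n_topics, token_budget, seed) {
  if (length(pubs) == 0L) stop("no publications to group", call. = FALSE)
  abstracts <- vapply(pubs, function(p) p$abstract, character(1))
  if (all(!nzchar(abstracts))) {
    stop("all abstracts are empty; use the MeSH strategy instead", call. = FALSE)
  }
  if (any(!nzchar(abstracts))) {
    stop("every publication entering abstract grouping needs a non-empty ",
         "abstract", call. = FALSE)
  }
  sizes <- vapply(abstracts, count_tokens, integer(1))
  if (any(sizes > token_budget)) {
    stop("token_budget (", token_budget, ") smaller than a single abstract (",
         max(sizes), " tokens)", call. = FALSE)
  }
  if (length(pubs) == 1L) return(list(pubs))
  k <- min(as.integer(n_topics), length(pubs))
  model <- suppressWarnings(fit_lda(as.list(abstracts), n_topics = k, seed = seed))
  topics <- vapply(seq_along(pubs), function(i)
    dominant_topic(model, i), integer(1))
  groups <- list()
  for (topic in sort(unique(topics))) {
    idx <- which(topics == topic)
    # greedy split in input order when a group exceeds the budget
    current <- integer()
    used <- 0L
    for (i in idx) {
      if (length(current) > 0L && used + sizes[i] > token_budget) {
        groups[[length(groups) + 1L]] <- pubs[current]
        current <- integer(); used <- 0L
      }
      current <- c(current, i)
      used <- used + sizes[i]
    }
    if (length(current) > 0L) groups[[length(groups) + 1L]] <- pubs[current]
  }
  groups
}

#' Generate a profile from abstracts by divide-and-conquer summarization
#'
#' The abstract strategy: publications are grouped by dominant LDA topic
#' (with greedy budget splitting), each group's abstracts are condensed by
#' one backend call, and the per-group summaries are combined by a final
#' call - `k` groups cost exactly `k + 1` backend calls. Intermediate
#' summaries are retained in the provenance log.
#'
#' @inheritParams generate_profile_mesh
#' @param combine_template Template for the final combining call.
#' @param n_topics LDA topics for grouping; default 30 capped at the number
#'   of publications.
#' @param token_budget Per-group token budget; default half the backend's
#'   context limit.
#' @param seed Integer seed for the LDA grouping.
#' @return Profile text with attribute `provenance`.
#' @export
generate_profile_abstract <- function(dossier, backend,
                                      template = default_template("abstract"),
                                      combine_template = default_template("combine"),
                                      n_topics = 30L, token_budget = NULL,
                                      seed, max_output_tokens = 512L) {
  pubs <- Filter(function(p) nzchar(p$abstract), dossier$publications)
  if (length(pubs) == 0L) {
    stop("all abstracts are empty; use the MeSH strategy instead", call. = FALSE)
  }
  if (is.null(token_budget)) token_budget <- backend$context_limit %/% 2L
  groups <- chunk_abstracts_by_topic(pubs, n_topics, token_budget, seed)
  log <- list()
  partials <- character(length(groups))
  for (g in seq_along(groups)) {
    material <- paste(vapply(groups[[g]], function(p) p$abstract, character(1)),
                      collapse = "\n")
    prompt <- render_prompt(template, material)
    res <- call_backend(backend, prompt, max_output_tokens, log)
    partials[g] <- res$out
    log <- res$log
  }
  final_prompt <- render_prompt(combine_template,
                                paste(partials, collapse = "\n"))
  res <- call_backend(backend, final_prompt, max_output_tokens, log)
  structure(res$out, provenance = res$log)
}

#' Paraphrase a human-written profile
#'
#' One backend call over the human profile; the paraphrase serves as the
#' evaluation baseline document (a text that is semantically faithful to
#' the reference while lexically free to vary).
#'
#' @param human_profile Non-empty profile text.
#' @inheritParams generate_profile_mesh
#' @return Paraphrased text with attribute `provenance`.
#' @export
paraphrase_profile <- function(human_profile, backend,
                               template = default_template("paraphrase"),
                               max_output_tokens = 512L) {
  if (!is.character(human_profile) || length(human_profile) != 1L ||
      !nzchar(human_profile)) {
    stop("human_profile must be a non-empty text", call. = FALSE)
  }
  prompt <- render_prompt(template, human_profile)
  res <- call_backend(backend, prompt, max_output_tokens, list())
  structure(res$out, provenance = res$log)
}
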
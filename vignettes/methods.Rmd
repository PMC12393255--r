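---
title: "Profiling scientific interests from publication records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling scientific interests from publication records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scholarprofiler)
```

This vignette documents the models behind `scholarprofiler`, the parameter
choices that matter, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a
committed choice had to be made.

## The problem

A research-interest profile is a short narrative stating what a scientist
works on. Writing one by hand is easy; keeping hundreds of them current
across an institution is not. The package's pipeline turns a researcher's
PubMed record into such a narrative and — because machine-written
narratives differ from self-written ones in characteristic ways — pairs
generation with an evaluation suite that measures those differences along
lexical, semantic, syntactic, topical and human-agreement axes.

## Record filtering

Two filters concentrate the dossier on work the researcher actually drove:

* **Recency**: a closed window of `window_years` calendar years ending at
  `reference_year` (default 10). The reference year is an explicit input,
  never the wall clock, so a run is reproducible by construction.
* **Authorship position**: the researcher must sit in the first three or
  the last three byline positions (`first3last3`, the default). In
  biomedical publishing the first block marks the researchers who did the
  work and the last block the senior/supervising authors; middle positions
  on large collaborations carry little signal about personal focus. A
  stricter variant (`first3senior`: first block, or the single final
  position) is available. On bylines of six or fewer authors the blocks
  overlap; the overlap resolves to the first block.

Name matching is deliberately coarse — case-folded surname plus first
given-initial, with the dossier affiliation as a substring tie-break when
several authors share a surname. Proper author-name disambiguation is a
known hard problem and out of scope; the matching rule is the documented
limitation, not a hidden heuristic.

Records with no publication year are excluded with a warning rather than
guessed at.

## Profile generation

Both strategies run over a backend contract: `generate(prompt,
max_output_tokens)` plus a declared `context_limit` and determinism flag.
The packaged default is a deterministic extractive summarizer — sentences
of the prompt material are ranked by the summed TF-IDF of their words
(each sentence a document of the within-material corpus), the top five are
kept (ties to the earlier sentence) and emitted in original order. It is
not a language model and does not pretend to be one; it exists so that
every pipeline stage has a reproducible, offline implementation whose
outputs tests can assert on bit for bit. Remote-LLM adapters plug into the
same contract.

**MeSH-based generation** pools the dossier's unique MeSH headings and
splits them into two buckets by MeSH tree branch: any tree number under
the health branches (C diseases, F psychology/psychiatry, G phenomena and
processes) puts a term in the health bucket; a term whose tree numbers all
fall under the methodology branches (E analytical/diagnostic techniques, L
information science, V publication characteristics) goes to methodology;
anything else is left unassigned and listed with the methodology keywords
in the prompt. A term qualifying for both goes to health, since profiles
foreground health topics. The split is a deterministic vocabulary lookup,
not an extra model call, so it is testable without a backend. The branch
sets are configurable.

**Abstract-based generation** is two-level map-reduce. Abstracts are
grouped by dominant LDA topic; groups exceeding the per-group token budget
are split greedily in input order; each group is condensed by one backend
call and a final call merges the partial summaries, so `k` groups cost
exactly `k + 1` calls. Token budgets are checked with whitespace tokens
times an inflation factor of 1.3 when the backend declares no tokenizer —
a deliberate overestimate of subword inflation for English scientific
prose, erring toward smaller chunks rather than overflow.

**One-shot prompts.** Every prompt carries exactly one worked example
(instruction, example material, example profile). The templates are plain
editable text files under `inst/templates/`; the packaged wording is
generic scaffolding, and users adapting the pipeline to a real LLM should
replace it with an example drawn from their own corpus.

**Paraphrase baseline.** The human-written profile is paraphrased by one
backend call. Its role in evaluation is diagnostic: a paraphrase is
semantically equivalent to the reference while lexically free, so any
metric that scores it low is demonstrably blind to semantics.

## Evaluation metrics

**Lexical.** BLEU, ROUGE-L and METEOR are implemented from their
definitions over lower-cased, punctuation-stripped whitespace tokens
(tokenization is configurable by tokenizing upstream). BLEU is the
original unsmoothed form — the geometric mean of clipped n-gram precisions
(n = 1..4) times the brevity penalty — so any zero precision zeroes the
score; add-one smoothing sits behind a flag because profile-length texts
rarely need it. ROUGE-L is the LCS form with F = (1+β²)PR/(R+β²P), β = 1.
METEOR uses staged unigram alignment (exact, then an optional stemmer
stage, then an optional synonym stage; both stages are pluggable contracts
and the synonym stage defaults off since no lexical database ships),
F-mean weighted toward recall (α = 0.9), and the fragmentation penalty
γ(chunks/matches)^β with γ = 0.5, β = 3. One point was genuinely open: the
original METEOR chooses among alignments by minimizing crossings. This
package pairs occurrences monotonically in order, which is deterministic,
linear-time, and identical on the cases that matter for profile texts
(exact repetitions aside, the two rules coincide); it is the package's
committed operationalization.

**Vocabulary shift.** Each profile becomes a TF-IDF weight vector
(tf · ln(N/df), natural log, no add-one; document frequencies over all
profile documents of the evaluation run), the pair's vectors are smoothed
into distributions over their union vocabulary by adding ε = 1e-9 to every
term and renormalizing, and the Kullback–Leibler divergence
D(human ‖ machine) is reported in nats. Three choices deserve note:

* *Direction.* The human profile is the reference distribution: the
  divergence asks how badly the machine profile's vocabulary covers it.
  Both directions and the symmetrized mean are exposed via a flag.
* *Smoothing.* Raw KL between profiles with any non-overlapping vocabulary
  is infinite; finite reported values imply smoothing of some form. The
  additive ε is the simplest choice with a controlled limit (as ε → 0 the
  distribution converges to the normalized weights).
* *Corpus.* Document frequencies must come from the run-level corpus, not
  from the compared pair alone. On a two-document corpus every shared term
  has df = N and idf = 0, which deletes exactly the shared vocabulary from
  the comparison and can invert the expected ordering between
  high-overlap and low-overlap pairs. The batch interface therefore pools
  all human and machine profiles of a run for df, and the tests construct
  background corpora the same way.
* *Mode.* Whether the underlying weights should be TF-IDF or raw term
  frequencies is ambiguous in principle; both modes are implemented and
  TF-IDF-normalized is the default.

**Novelty.** The count of distinct, stop-word-filtered human-profile terms
absent from every machine text, restricted to recognized MeSH concepts so
that typos and function words do not inflate it. MeSH matching is
case-insensitive with hyphen/space normalization, includes entry terms
(synonyms) as well as descriptor names, and finds multi-word concepts by a
longest-match left-to-right phrase scan. Including entry terms is a
committed choice: a human writing "orphan diseases" where the machine
writes "rare diseases" is exactly the conceptual-vocabulary gap the count
is meant to surface. The count is antitone in the machine corpus by
construction — adding machine text can only remove novelty.

**Embedding similarity.** BERTScore-style greedy matching: precision is
the mean over candidate tokens of their best cosine against the reference,
recall the symmetric quantity, F1 their harmonic mean; no idf weighting,
no baseline rescaling. The embedder is a contract (`tokens → matrix`). The
packaged default maps each token to a fixed unit Gaussian vector keyed by
a polynomial hash of the token — deterministic across sessions, requiring
no download. It is a *static* embedder: identical tokens always match at
cosine 1 and unrelated tokens sit near orthogonality in 64 dimensions, so
scores behave like a soft unigram overlap. That is sufficient for testing
the matching algebra and for relative comparisons within a run; absolute
values are not comparable to scores from a contextual model, and a
contextual adapter should be plugged in for real analyses.

**Syntax.** Five measures over dependency parses: PoS-tag frequency
percentages; maximum root-to-token path length per sentence (depth, in
edges — node counting shifts it by one and sits behind a flag); mean
root-to-token path length over non-root tokens (complexity; single-token
sentences score 0 by convention); attachment ambiguity; and per-tag
distinct-word counts (lexical diversity). Ambiguity required an
operationalization: the package measures the mean token length of maximal
modifier phrases — subtrees headed by `nmod`, `obl`, `acl`, `acl:relcl` or
`advcl` tokens — that are preceded in the sentence by at least two
plausible attachment sites (NOUN/PROPN/VERB/AUX tokens outside the
phrase). This captures the classic PP-attachment pattern ("saw the man
with the telescope") deterministically from a parse, which makes it
testable; it is an interpretation, and it is flagged as such. Parsing
itself is a contract: CoNLL-U files are read directly, hand-built parses
drive the tests, and the packaged fallback parser produces flat star
parses that carry no linguistic signal (it exists only so the pipeline can
run end to end without a model — syntactic numbers from it are
placeholders, which is why documented analyses should use real parses).

**Agreement.** Gwet's AC1 for multiple raters on categorical scales:
observed agreement is the mean over items of the pairwise-agreement
fraction, chance agreement is Σπ(1−π)/(Q−1) over category prevalences, and
AC1 = (Pa−Pe)/(1−Pe). Unlike kappa, the chance term shrinks as prevalences
skew, which keeps the coefficient stable on the skewed rating
distributions quality surveys produce. Items rated by fewer than two
raters are dropped and tallied; Pe = 1 is reported as undefined rather
than divided through. Stratified AC1 recomputes the coefficient
independently within item bands. Paired t-tests are two-sided via
`stats::t.test`; identical score columns are reported as degenerate rather
than erroring. No multiple-testing correction is applied by default,
matching per-metric reporting conventions; Holm adjustment is available
behind a flag.

## Topic model and stability

The LDA implementation is a collapsed Gibbs sampler (compiled via Rcpp)
drawing through R's RNG, so `set.seed` makes fits exactly reproducible —
a hard requirement, since dominant-topic assignment feeds both abstract
chunking and the stability analysis. Defaults: α = 0.1, η = 0.1, 500
sweeps. The sparse document prior reflects that a short abstract usually
expresses one or two topics; with a flat prior (50/K) and fewer sweeps the
chain occasionally leaves two planted topics merged on separable corpora,
which a sparse prior and a longer chain eliminate in recovery diagnostics.
Dominant topics are the argmax of the document-topic distribution with
ties broken toward the lowest index. For documents outside the training
set the posterior is computed from the fitted topic-word probabilities
under a single-topic-proportion approximation in log space;
out-of-vocabulary tokens are ignored.

The diversity score for a researcher is unique dominant topics divided by
publications with usable abstracts (abstract-less publications are
excluded from numerator and denominator and tallied). Scores below 0.3
are classed stable, above 0.7 shifting; the thresholds are strict, so
exactly 0.3 or 0.7 is intermediate. A researcher with one publication is
necessarily "shifting" (diversity 1) — the band is a statement about the
ratio, not a biography. Topic assignment is year-independent; years only
group the heatmap table.

## Synthetic data: what it emulates, what it does not

The generator plants exactly the structure the metrics assume, with
ground truth emitted alongside so tests never re-derive it:

* per-researcher publication counts drawn from realistic band frequencies
  (0–29 through ≥ 120, weighted as in a mid-sized academic-medical
  faculty), overridable with a uniform range for small test corpora;
* bag-of-words abstracts from per-topic vocabularies with a configurable
  overlap fraction (0 = fully separable);
* stable researchers with a single planted topic over ≥ 4 publications,
  shifting researchers with all-distinct topics, the remainder mixing a
  few topics (default mix 48.8% stable / 4.3% shifting);
* MeSH headings drawn from per-topic descriptor pools present in the
  emitted fixture vocabulary, with tree numbers alternating between
  methodology and health branches;
* human-style profiles built from topic keywords plus planted novel MeSH
  terms from a reserved pool that never reaches any abstract;
* authorship positions (first/last/middle) with known placement;
* rating tables where each rater copies the item's latent category with
  probability *a* and otherwise draws uniformly from the remaining
  categories, so *a* = 1 forces AC1 = 1 and *a* = 1/Q drives it to 0.

One global seed fans out to fixed per-component substreams, so adding a
component does not shift existing draws and the whole corpus is
byte-reproducible.

What passing tests on this corpus show — and do not show. Bag-of-words
abstracts have no grammar, so the syntactic suite is exercised on
hand-built parse fixtures instead, by design. Synthetic vocabularies are
cleanly separable where real abstracts share a long-tailed common
vocabulary; planted-recovery results bound what the algorithms do under
their assumptions, not what they achieve on a real faculty corpus.
Likewise the extractive backend makes generation reproducible but trivially
non-abstractive; absolute metric values from synthetic runs characterize
the harness, and only relative and structural claims (orderings,
invariances, recoveries, calibrations) transfer.

## Numerical and degenerate-input conventions

* Empty candidate or reference sequences score 0 (with a warning) in
  BLEU/ROUGE/METEOR/BERTScore rather than erroring, so batch runs survive
  empty profiles; profiles empty after stop-word removal make KL undefined
  and are reported missing.
* TF-IDF requires ≥ 2 documents; a single-document corpus is an error
  naming the reason (document frequency is undefined).
* The extractive backend breaks score ties toward the earlier sentence;
  dominant-topic ties break toward the lower index; both rules make
  outputs order-stable.
* `to_distribution` rejects ε ≤ 0; `kl_divergence` requires identical
  supports and treats p = 0 terms as contributing zero.
* Degenerate paired t-tests (zero difference variance) and degenerate AC1
  tables (Pe = 1) are reported as such, never silently coerced.
* Report bundles embed a config hash and seeds but no timestamps, so two
  identical runs produce byte-identical files.

Problem sizes in the shipped tests and the acceptance script — corpora of
5–20 researchers with 4–12 publications each, 3–5 planted topics, rating
tables up to 1000 items, exhaustive metric sweeps over 3-symbol sequences
of length ≤ 5 — were chosen as the smallest sizes at which every planted
structure is recoverable and every exhaustive check is genuinely
exhaustive.

## Known limitations

* Author-name disambiguation is surname + initial + affiliation substring;
  common names across institutions will confound dossiers.
* The MeSH methodology/health split assigns by tree branch only; terms
  outside the configured branches land unassigned rather than being
  inferred.
* The packaged embedder is static; BERTScore absolute values are not
  comparable to contextual-model scores.
* The flat fallback parser yields placeholder syntax numbers; real
  analyses need CoNLL-U input or a real parser behind the contract.
* METEOR's alignment and the ambiguity measure are committed
  operationalizations of underspecified definitions, as documented above.
* KL magnitudes depend on ε and on the df corpus; compare values only
  within a run configuration.
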
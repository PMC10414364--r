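---
title: "Surveillance of potential adverse events in clinical note text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance of potential adverse events in clinical note text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most text-based adverse-event (AE) detection starts from a predefined list
of events and searches notes for matching words. That design cannot find
harms nobody thought to look for, and it misses events the note writer
never attributed to a treatment ("unattributed" AEs). This package
implements an unsupervised alternative: contrast the notes of a target
admission group (for example, transfused patients, or the most recent
year) against a comparison group (non-transfused patients, or the prior
year), keep only the terms that statistically separate the groups, topic-
model the term-filtered target documents, and surface the documents and
term time-trends a clinician should read. Nothing about the events of
interest is specified in advance; the contrast itself decides which terms
matter.

```{r, eval = FALSE}
library(shakespeare)
```

## Pipeline

1. **Assemble.** All notes of one admission are concatenated in
   chronological order into a single document (`assemble_documents()`),
   after removing admissions of patients under 16 and (by construction)
   admissions without notes (`filter_cohort()`).
2. **Deduplicate.** Concatenated notes repeat boilerplate sentences,
   paragraphs and list items verbatim; replicates distort term statistics.
   `dedup_documents()` keeps the first occurrence of each unit.
3. **Vectorize.** Documents become bag-of-words count vectors over an
   n-gram vocabulary (n = 1–5), `build_vocabulary()` +
   `vectorize_documents()`. The PII mask token is removed and text is
   lowercased; punctuation, numerals and stop words are kept because in
   clinical text they carry information (vitals, doses, abbreviations).
4. **Select terms.** `select_terms_ensemble()` (group contrast) or
   `select_terms_temporal()` (recent vs. prior period) picks the terms
   significant for the target side.
5. **Topic-model and review.** `fit_lda()` on the term-trimmed target
   matrix; `select_review_set()`, `max_topic_table()` and the trend
   functions produce the review artifacts.

`run_pipeline()` chains the stages with per-stage artifacts and a JSON
manifest; the `exec/shakespeare` script exposes the same stages on the
command line.

## Text segmentation and duplicate matching

Clinical sentences do not reliably end in punctuation: newlines both break
sentences and wrap text, and numbered/bulleted lists are common.
`segment_units()` therefore splits on sentence-final periods and question
marks *and* on newline boundaries, while list markers (`1.`, `a.`),
decimal numbers (`1.23`) and a small abbreviation list (`dr.`, `e.g.`, …)
never split. Duplicate matching is exact, on a normalized key (lowercased,
whitespace collapsed), and applies strictly within one admission document:
cross-admission boilerplate is a different phenomenon and removing it
would delete genuinely shared clinical language. Unit granularity
(sentence/list item) is a fixed design choice; fuzzy near-duplicate
matching is out of scope. Dedup is idempotent, keeps the first occurrence
of every key, and never changes the set of distinct keys.

## Vocabulary and counting

Tokenization splits on whitespace only, so `hr.` and `hr` are distinct
terms — deliberately, since punctuation-bearing variants are real tokens
of this register. Multiword terms are admitted by an adjacent-unit
cohesion score

$$\mathrm{score}(a,b) = \frac{(c_{ab} - \delta)\,N}{c_a\, c_b},$$

with discount $\delta = 5$, admission when the score exceeds 10 and
$c_{ab} \ge 5$ (all three exposed as arguments). Passes repeat, merging
admitted pairs greedily left-to-right, until phrases reach `max_n` words.
Counting uses greedy longest-match: tokens absorbed into an admitted
phrase are not also counted as their component unigrams. Whether component
unigrams should additionally be counted is genuinely open; both behaviors
exist behind `count_nested`, with suppression the default because it keeps
the conservation property (trimming a matrix to a sub-vocabulary that
retains its phrases equals re-vectorizing with that sub-vocabulary).

## Term selection

**Group contrast (ensemble).** Ridge logistic regression (via glmnet,
penalty $\lambda = 1/n$ by default) and multinomial naive Bayes (Laplace
$\alpha = 1$) are fit to label target vs. comparison documents on raw
counts. The selection is the union of three paths designed to catch
common, infrequent and rare target-significant terms respectively: the
top `k_lr` terms by positive LR coefficient, the top `k_nb` terms by
lowest NB log-probability ratio
$\log P(t\mid C) - \log P(t\mid T)$, and target-exclusive terms with at
least `exclusive_min_count` occurrences. A `margin` excludes terms without
strictly positive evidence, so identical groups select nothing. The
published study-scale list sizes cannot be pinned down without the
original data, so `k_lr`, `k_nb` and the exclusive count are explicit
configuration with defaults documented as non-canonical.

**Temporal.** Both models are refit on all documents of the two periods
(no train/test split; the recent period is the positive class). The
classification set is the union of the top-5000 positive-coefficient LR
terms and the 5000 lowest-ratio NB terms. The frequency set is the union
of (a) terms in fewer than 10% of prior-period documents whose *raw*
corpus count grew by at least 30% — raw by default, with a
per-document-normalized variant behind `normalize_frequency` — and (b)
terms absent from the prior period that appear in the recent one, minus
digit-only terms (every whitespace token matching `^[0-9]+$`). The
selection is the intersection of the two sets. Rule (a) requires at least
one prior-period occurrence; a never-seen term belongs to rule (b), which
applies the digit filter — counting zero-count terms under (a) would let
digit-only terms bypass that filter. Ties in any top-k ranking break by
score then lexicographic term, so selections are reproducible.

`evaluate_classifiers()` reports weighted-average F1 on a stratified
held-out split, mirroring how the two models are compared before refitting.

## Topic model

`fit_lda()` implements latent Dirichlet allocation with batch mean-field
variational inference, written in the package. Variational inference was
chosen over collapsed Gibbs for exact determinism under a fixed seed;
results may differ slightly in numeric detail from sampler-based fits.
Priors are symmetric, $\alpha = \eta = 1/K$, convergence is declared when
the mean absolute change of the document-topic posterior between corpus
passes falls below `1e-4` (at most 100 passes).

Two consequences of the model are used as checks throughout:

* each document-topic row is a probability vector (sums to 1 within
  `1e-6`), hence no document can have more than $\lfloor 1/t \rfloor$
  topics with score $\ge t$ (33 at the 0.03 threshold);
* a document with zero in-vocabulary terms keeps its variational
  posterior at the prior, so its topic distribution is exactly uniform:
  $1/K$ per topic, 0.022 at $K = 45$ — the floor score a filtered-out
  document receives.

"Term scores" are reported as expected topic-term pseudo-counts
(unnormalized), which is why top-term scores look like large counts; a
normalized probability view is in `$beta`. `tune_k()` fits a grid of K
and reports the diagnostics used to choose one — topics with a top
document score of at least 0.5 ("coherent" in this method's usage), weak
topics, and mean topics per document at the 0.03 threshold. The choice of
K itself is human judgment, not an automated coherence metric.

## Review selection and trends

`select_review_set()` returns the top-k documents per topic (ties by
ascending document id), the documents with the most topics at or above the
significant-score threshold (strict count order), and an independent
uniform random sample — deliberately not disjoint from the other lists.
Defaults follow the method's published review protocol: 3 documents per
topic, 7 multi-topic documents, 24 random documents at threshold 0.03.
Clinical exclusion of random-sample documents is manual by nature; the
sampler only accepts an explicit `exclude_ids` list.

`quarterly_proportions()` evaluates a presence criterion — a small boolean
grammar over word atoms (whole-token match after the vectorizer's
normalization, `*` allowing any suffix), code atoms and stay-length
predicates — per admission, assigning admissions to the calendar quarter
of their first note. `fit_trend()` fits unweighted OLS of proportion on
quarter index, matching the slope / 95% CI / p-value presentation
conventional in surveillance plots; a binomial-GLM alternative (logit
scale) sits behind `method = "binomial"`. Degenerate series are handled
explicitly: a perfectly constant series has slope 0 and p = 1, a perfect
non-constant line has a zero-width CI. `fisher_exact()` computes the
two-sided p by full hypergeometric enumeration (summing the probabilities
of tables no more probable than the observed one).

## The synthetic generator

Real critical-care note tables are credential-restricted, so every stage
is exercised on `generate_cohort()` corpora with recorded ground truth.
The generator emulates the *structural* properties the pipeline must
survive: several note types per admission with strictly increasing
timestamps, sentences ended by periods or bare newlines plus numbered
list blocks, verbatim replicate sentences planted within admissions
(`duplicate_fraction`), a PII mask token in at least 10% of notes,
misspellings and abbreviations in the lexicon, numeral noise,
group-specific signal terms injected per document at configured rates,
and terms whose per-quarter document prevalence follows a linear slope.
It does **not** attempt realistic clinical language, grammar, or
correlated comorbidity structure — so passing tests demonstrate that the
machinery recovers planted statistical structure under the stated noise,
not that it would surface true clinical AEs from real notes.

Standard study conditions used by the tests, fixed once: 300 admissions
per group with 20 signal terms at document rates 0.6 (target) vs 0.05
(comparison) for selection recovery, evaluated over 3 replicate seeds;
binomial trend series of 28 quarters at 500 admissions per quarter with
true slope 0.005 per quarter for CI coverage, and slope 0 for the nominal
5% false-positive rate; a 200-document corpus fitted at K = 45 for the
topic-score properties; and 2 × 100 documents with disjoint vocabularies
for 2-topic class recovery. Selection recovery is scored as recall of the
injected terms and the false-selection rate, defined as the fraction of
non-injected vocabulary terms selected (a false-positive rate over the
candidate vocabulary). The selector is run with `k_lr = k_nb = 25` and
`margin = 1e-6` on this benchmark — list sizes on the order of the
planted signal, as a practitioner would choose facing a vocabulary of
several hundred terms.

## Known limitations

* Exact-match dedup misses near-duplicates (reworded boilerplate).
* The collocation score is applied to adjacent units only; long-range
  skip-grams are not scored.
* OLS on quarterly proportions ignores denominator variation across
  quarters; the binomial GLM flag addresses this at the cost of the
  familiar proportion-scale slope.
* LDA results depend on K and on the variational initialization seed;
  both are recorded in every result object so fits are reproducible.
* Group labels are taken as given (mapping file or generator truth);
  deriving them from structured data is outside the package's scope.
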
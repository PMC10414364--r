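# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

# standard synthetic corpus: generated cohort -> filtered, assembled,
# deduplicated documents -> normalized texts -> term matrix split by group
std_corpus <- function(n_per_group = 50, seed = 3, ...) {
  key <- paste(n_per_group, seed,
               paste(deparse(substitute(list(...))), collapse = ""), sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cohort <- generate_cohort(synth_config(n_admissions_per_group = n_per_group,
                                         seed = seed, ...))
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  notes <- filter_cohort(load_notes(file.path(dir, "notes.csv")))
  docs_raw <- assemble_documents(notes, groups = cohort$truth$group)
  docs <- dedup_documents(docs_raw)
  texts <- setNames(normalize_text(docs$text, "[**PII**]"), docs$admission_id)
  vocab <- build_vocabulary(texts)
  tm <- vectorize_documents(texts, vocab)
  grp <- cohort$truth$group[rownames(tm$counts)]
  out <- list(cohort = cohort, dir = dir, docs_raw = docs_raw, docs = docs,
              texts = texts, vocab = vocab, tm = tm, group = grp,
              target = subset_tm(tm, grp == "target"),
              comparison = subset_tm(tm, grp == "comparison"))
  .fixture_cache[[key]] <- out
  out
}

subset_tm <- function(tm, keep) {
  structure(list(counts = tm$counts[keep, , drop = FALSE], terms = tm$terms),
            class = "term_matrix")
}

# small term matrix straight from texts against an explicit vocabulary
tm_from <- function(texts, vocab) vectorize_documents(texts, vocab)

# two document classes with disjoint vocabularies (topic-recovery fixture)
disjoint_corpus <- function(n_per_class = 60, n_tokens = 40, seed = 9) {
  vocab_a <- paste0("alpha", 1:15)
  vocab_b <- paste0("beta", 1:15)
  with_seed_test(seed, {
    texts <- c(
      vapply(seq_len(n_per_class), function(i)
        paste(sample(vocab_a, n_tokens, replace = TRUE), collapse = " "),
        character(1)),
      vapply(seq_len(n_per_class), function(i)
        paste(sample(vocab_b, n_tokens, replace = TRUE), collapse = " "),
        character(1))
    )
  })
  names(texts) <- sprintf("D%03d", seq_along(texts))
  list(texts = texts, class = rep(c("A", "B"), each = n_per_class),
       vocab_a = vocab_a, vocab_b = vocab_b,
       tm = vectorize_documents(texts, c(vocab_a, vocab_b)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# independent hypergeometric enumeration oracle for a 2x2 Fisher test,
# written with choose() only (no dhyper)
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
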
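test_that("document-topic rows are probability vectors and empty documents sit at the prior", {
  dc <- disjoint_corpus(n_per_class = 30)
  texts <- c(dc$texts, empty = "zzz-out-of-vocab")
  tm <- vectorize_documents(texts, c(dc$vocab_a, dc$vocab_b))
  fit <- fit_lda(tm, K = 5, seed = 2)
  expect_lt(max(abs(rowSums(fit$doc_topic) - 1)), 1e-6)
  expect_true(all(fit$doc_topic >= 0))
  expect_equal(unname(fit$doc_topic["empty", ]), rep(1 / 5, 5))
})

test_that("a two-topic fit on disjoint vocabularies recovers the generating classes", {
  dc <- disjoint_corpus(n_per_class = 60)
  fit <- fit_lda(dc$tm, K = 2, seed = 4)
  assigned <- max.col(fit$doc_topic)
  agree <- max(mean(assigned == as.integer(factor(dc$class))),
               mean(assigned == 3 - as.integer(factor(dc$class))))
  expect_gte(agree, 0.95)
  # topic-term scores concentrate on the class vocabulary
  s <- summarize_topics(fit, top_n = 10)
  tops <- strsplit(s$top_terms, ", ")
  one_class <- vapply(tops, function(t)
    all(t %in% dc$vocab_a) || all(t %in% dc$vocab_b), logical(1))
  expect_true(all(one_class))
})

test_that("fitting is deterministic under a fixed seed and validates inputs", {
  dc <- disjoint_corpus(n_per_class = 20)
  f1 <- fit_lda(dc$tm, K = 3, seed = 7)
  f2 <- fit_lda(dc$tm, K = 3, seed = 7)
  expect_identical(f1$doc_topic, f2$doc_topic)
  expect_identical(f1$term_topic, f2$term_topic)
  f3 <- fit_lda(dc$tm, K = 3, seed = 8)
  expect_false(identical(f1$doc_topic, f3$doc_topic))

  expect_error(fit_lda(dc$tm, K = 1), "K must be >= 2")
  expect_error(fit_lda(subset_tm(dc$tm, 1:3), K = 5), "at least K documents")
})

test_that("no document exceeds the floor(1/threshold) bound on significant topics", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  fit <- fit_lda(cx$target, K = 8, seed = 1)
  expect_lte(max(rowSums(fit$doc_topic >= 0.03)), floor(1 / 0.03))
  expect_lte(max(rowSums(fit$doc_topic >= 0.2)), floor(1 / 0.2))
})

test_that("tune_k reports per-K diagnostics deterministically", {
  dc <- disjoint_corpus(n_per_class = 30)
  tuned <- tune_k(dc$tm, K_list = c(2, 3), seed = 5)
  expect_length(tuned, 2)
  expect_equal(tuned[[1]]$K, 2L)
  # by construction both topics of the K=2 fit dominate their class documents
  expect_equal(unname(tuned[[1]]$diagnostics["coherent_topics"]), 2)
  tuned2 <- tune_k(dc$tm, K_list = c(2, 3), seed = 5)
  expect_identical(lapply(tuned, `[[`, "diagnostics"),
                   lapply(tuned2, `[[`, "diagnostics"))
  expect_error(tune_k(dc$tm, integer()), "non-empty")
})

test_that("topic summaries tally score bands correctly", {
  doc_topic <- rbind(c(0.97, 0.03), c(0.6, 0.4), c(0.45, 0.55), c(0.15, 0.85))
  rownames(doc_topic) <- paste0("d", 1:4)
  fake <- structure(list(K = 2L, doc_topic = doc_topic,
                         term_topic = matrix(c(5, 1, 2, 8), 2, 2,
                                             dimnames = list(NULL, c("t1", "t2"))),
                         beta = NULL, terms = c("t1", "t2")),
                    class = "lda_result")
  s <- summarize_topics(fake, top_n = 2)
  t1 <- s[s$topic == 1, ]; t2 <- s[s$topic == 2, ]
  # hand tally for topic 1: 0.97, 0.6 in >=0.5; 0.45 in [0.2,0.5); 0.15 in [0.1,0.2)
  expect_equal(unname(unlist(t1[, c("n_0.5", "n_0.2", "n_0.1", "n_0.03")])),
               c(2, 1, 1, 0))
  # topic 2: 0.55, 0.85 in >=0.5; 0.4 in [0.2,0.5); 0.03 in [0.03,0.1)
  expect_equal(unname(unlist(t2[, c("n_0.5", "n_0.2", "n_0.1", "n_0.03")])),
               c(2, 1, 0, 1))
  expect_equal(s$topic, c(1, 2))           # sorted by top doc score desc
  expect_equal(s$top_term_score, c(5, 8))

  uniform <- structure(list(K = 3L,
                            doc_topic = matrix(1 / 3, 6, 3),
                            term_topic = matrix(1, 3, 4,
                                                dimnames = list(NULL, letters[1:4])),
                            beta = NULL, terms = letters[1:4]),
                       class = "lda_result")
  su <- summarize_topics(uniform, top_n = 2)
  expect_equal(length(unique(su$n_0.2)), 1)
  expect_equal(length(unique(su$n_sig)), 1)
})
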
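test_that("identical groups select nothing under a positive evidence margin", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  same <- cx$target
  res <- select_terms_ensemble(same, same, k_lr = 100, k_nb = 100,
                               exclusive_min_count = 3, margin = 1e-6)
  expect_length(res$selected, 0)
})

test_that("ensemble selection validates inputs", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  empty <- subset_tm(cx$tm, rep(FALSE, nrow(cx$tm$counts)))
  expect_error(select_terms_ensemble(cx$target, empty), "non-empty")
  other <- vectorize_documents(c(a = "x y"), c("x", "y"))
  expect_error(select_terms_ensemble(cx$target, other), "share one vocabulary")
})

test_that("ensemble selection recovers injected signal terms", {
  cx <- std_corpus(n_per_group = 50, seed = 3)
  truth <- cx$cohort$truth
  res <- select_terms_ensemble(cx$target, cx$comparison,
                               k_lr = 25, k_nb = 25,
                               exclusive_min_count = 3, margin = 1e-6)
  recall <- mean(truth$signal_terms %in% res$selected)
  expect_gte(recall, 0.8)
  # every selected term carries at least one selection-path flag
  diag <- res$diagnostics[res$diagnostics$selected, ]
  expect_true(all(diag$path_lr | diag$path_nb | diag$path_exclusive))
  # determinism
  res2 <- select_terms_ensemble(cx$target, cx$comparison,
                                k_lr = 25, k_nb = 25,
                                exclusive_min_count = 3, margin = 1e-6)
  expect_identical(res$selected, res2$selected)
})

test_that("temporal frequency rules match a literal brute-force scan", {
  cx <- std_corpus(n_per_group = 100, seed = 11,
                   trend_terms = data.frame(
                     term = c("newdrug", "risingterm"),
                     slope = c(0.08, 0.03), base = c(0, 0.01)))
  q <- cx$cohort$truth$quarter[rownames(cx$tm$counts)]
  p2 <- subset_tm(cx$tm, q <= 4)
  p3 <- subset_tm(cx$tm, q > 4)
  res <- select_terms_temporal(p2, p3, k_lr = 50, k_nb = 50)

  # brute-force re-scan of the vocabulary with the rules applied literally
  c2 <- Matrix::colSums(p2$counts); c3 <- Matrix::colSums(p3$counts)
  df2 <- Matrix::colSums(p2$counts > 0); n2 <- nrow(p2$counts)
  terms <- p2$terms
  increased <- terms[c2 > 0 & df2 / n2 < 0.10 & c3 >= 1.3 * c2]
  digit_only <- vapply(strsplit(terms, " "),
                       function(t) all(grepl("^[0-9]+$", t)), logical(1))
  new_terms <- terms[c2 == 0 & c3 > 0 & !digit_only]
  expect_setequal(res$sets$frequency_increase, increased)
  expect_setequal(res$sets$new_terms, new_terms)
  expect_setequal(res$sets$frequency, union(increased, new_terms))

  # intersection law
  expect_true(all(res$selected %in% res$sets$classification))
  expect_true(all(res$selected %in% res$sets$frequency))
})

test_that("digit-only new terms are filtered; mixed terms survive", {
  vocab <- c("2007", "newword", "base")
  p2 <- vectorize_documents(c(a = "base base", b = "base"), vocab)
  p3 <- vectorize_documents(c(c = "base 2007 newword", d = "2007 newword base"),
                            vocab)
  res <- suppressWarnings(select_terms_temporal(p2, p3, k_lr = 10, k_nb = 10))
  expect_false("2007" %in% res$sets$new_terms)
  expect_true("newword" %in% res$sets$new_terms)
  expect_error(select_terms_temporal(subset_tm(p2, c(FALSE, FALSE)), p3),
               "empty period")
})

test_that("classifier evaluation scores a separable corpus perfectly and a permuted one near baseline", {
  dc <- disjoint_corpus(n_per_class = 40)
  p2 <- subset_tm(dc$tm, dc$class == "A")
  p3 <- subset_tm(dc$tm, dc$class == "B")
  ev <- evaluate_classifiers(p2, p3, split_fraction = 0.25, seed = 1)
  expect_equal(ev$lr$weighted_f1, 1.0)
  expect_equal(ev$nb$weighted_f1, 1.0)

  # permuting documents across the period labels destroys the signal
  perm <- with_seed_test(5, sample(nrow(dc$tm$counts)))
  mixed <- subset_tm(dc$tm, perm)
  half <- nrow(mixed$counts) %/% 2
  ev0 <- evaluate_classifiers(subset_tm(mixed, seq_len(half)),
                              subset_tm(mixed, (half + 1):nrow(mixed$counts)),
                              split_fraction = 0.25, seed = 1)
  expect_lt(ev0$lr$weighted_f1, 0.8)

  expect_error(evaluate_classifiers(p2, p3, split_fraction = 1), "degenerate split")
})

test_that("trim_matrix restricts columns without changing counts", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  full <- trim_matrix(cx$tm, cx$tm$terms)
  expect_equal(as.matrix(full$counts), as.matrix(cx$tm$counts))
  expect_error(trim_matrix(cx$tm, character()), "empty term selection")
  expect_error(trim_matrix(cx$tm, "no-such-term"), "not in vocabulary")
  sub <- with_seed_test(8, sample(cx$tm$terms, 50))
  trimmed <- trim_matrix(cx$tm, sub)
  expect_equal(Matrix::colSums(trimmed$counts)[sort(sub, method = "radix")],
               Matrix::colSums(cx$tm$counts)[sort(sub, method = "radix")])
})
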
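test_that("normalize_text removes the mask and lowercases, touching nothing else", {
  expect_equal(normalize_text("BP 120/80 [**MASK**] OK", "[**MASK**]"),
               "bp 120/80  ok")
  expect_equal(normalize_text("Pt Stable; 3.5mg!", "[**MASK**]"),
               "pt stable; 3.5mg!")
  expect_equal(trimws(normalize_text("[**MASK**]", "[**MASK**]")), "")
})

test_that("vocabulary admits collocations by cohesion score and is deterministic", {
  corpus <- c("a b", "a b", "c")
  # score for "a b": (2 - 0) * 5 / (2 * 2) = 2.5
  v <- build_vocabulary(corpus, max_n = 2, collocation_min_count = 2,
                        collocation_threshold = 2, delta = 0)
  expect_true(all(c("a", "b", "c", "a b") %in% v$terms))
  v_hi <- build_vocabulary(corpus, max_n = 2, collocation_min_count = 2,
                           collocation_threshold = 3, delta = 0)
  expect_false("a b" %in% v_hi$terms)

  uni <- build_vocabulary(c("x y", "y z z"), max_n = 1)
  expect_setequal(uni$terms, c("x", "y", "z"))

  cx <- std_corpus(n_per_group = 25, seed = 3)
  again <- build_vocabulary(cx$texts)
  expect_identical(cx$vocab$terms, again$terms)
  expect_false(is.unsorted(cx$vocab$terms))

  expect_error(build_vocabulary(character()), "empty corpus")
})

test_that("phrases grow beyond bigrams when cohesion persists", {
  corpus <- rep("acute renal failure", 20)
  v <- build_vocabulary(corpus, max_n = 3, collocation_min_count = 5,
                        collocation_threshold = 1, delta = 0)
  expect_true(any(lengths(strsplit(v$phrases, " ")) == 3))
})

test_that("vectorization counts terms, with greedy longest-match for phrases", {
  tm <- vectorize_documents(c(d1 = "a a b"), c("a", "b", "c"))
  expect_equal(as.numeric(tm$counts[1, ]), c(2, 1, 0))
  expect_equal(sum(vectorize_documents(c(d1 = ""), c("a"))$counts), 0)

  vocab <- c("mechanical", "ventilation", "mechanical ventilation", "weaned")
  tm2 <- vectorize_documents(c(d = "mechanical ventilation weaned mechanical"),
                             vocab)
  expect_equal(as.numeric(tm2$counts[1, vocab]), c(1, 0, 1, 1))
  tm3 <- vectorize_documents(c(d = "mechanical ventilation weaned mechanical"),
                             vocab, count_nested = TRUE)
  expect_equal(as.numeric(tm3$counts[1, vocab]), c(2, 1, 1, 1))
})

test_that("row sums equal a brute-force token counter on the synthetic corpus", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  uni_vocab <- build_vocabulary(cx$texts, max_n = 1)
  tm <- vectorize_documents(cx$texts, uni_vocab)
  oracle <- vapply(strsplit(cx$texts, "[[:space:]]+"),
                   function(t) sum(nzchar(t)), numeric(1))
  expect_equal(unname(Matrix::rowSums(tm$counts)), unname(oracle))
})

test_that("restricting a matrix to a sub-vocabulary equals re-vectorizing with it", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  uni_vocab <- build_vocabulary(cx$texts, max_n = 1)
  tm <- vectorize_documents(cx$texts, uni_vocab)
  sub <- with_seed_test(4, sample(uni_vocab$terms, length(uni_vocab$terms) %/% 2))
  sub <- sort(sub, method = "radix")
  trimmed <- trim_matrix(tm, sub)
  direct <- vectorize_documents(cx$texts, sub)
  expect_equal(as.matrix(trimmed$counts), as.matrix(direct$counts))
  # count conservation under restriction
  expect_equal(sum(trimmed$counts),
               sum(Matrix::colSums(tm$counts)[sub]))
})

test_that("term matrices round-trip through MatrixMarket serialization", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  path <- file.path(tempfile(), "m.mtx")
  dir.create(dirname(path))
  write_term_matrix(cx$tm, path)
  back <- read_term_matrix(path)
  expect_identical(back$terms, cx$tm$terms)
  expect_equal(as.matrix(back$counts), as.matrix(cx$tm$counts))
})
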
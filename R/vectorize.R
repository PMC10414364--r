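# Bag-of-words vectorization with collocation-admitted multiword terms.
#
# Tokenization splits on whitespace only: punctuation, numerals and stop
# words all carry clinical information (abbreviations, vitals, doses) and
# are kept. Multiword terms (n = 2..max_n) enter the vocabulary only when
# an adjacent-token cohesion score admits them.

#' Normalize document text
#'
#' Removes every occurrence of the PII mask token and lowercases the text.
#' Punctuation, numerals and stop words are deliberately untouched.
#'
#' @param text character vector of document texts
#' @param pii_mask literal mask token to delete (fixed string, not regex)
#' @return normalized texts
#' @export
normalize_text <- function(text, pii_mask = "[**PII**]") {
  tolower(gsub(pii_mask, "", text, fixed = TRUE))
}

.tokenize <- function(text) {
  toks <- strsplit(text, "[[:space:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

.n_words <- function(x) lengths(strsplit(x, " ", fixed = TRUE))

#' Build an n-gram vocabulary
#'
#' Unigrams are all distinct whitespace-delimited tokens. Longer terms are
#' grown iteratively: in each pass, an adjacent unit pair (a, b) is merged
#' into the phrase "a b" when its joint count is at least
#' `collocation_min_count` and its cohesion score
#' `(count(ab) - delta) * N / (count(a) * count(b))` exceeds
#' `collocation_threshold` (N = number of units in the pass). Passes repeat
#' until no pair is admitted or phrases reach `max_n` words. The vocabulary
#' is sorted lexicographically (C locale) for determinism.
#'
#' @param documents character vector of normalized document texts
#' @param max_n maximum phrase length in words (1–5)
#' @param collocation_min_count minimum joint count for phrase admission
#' @param collocation_threshold minimum cohesion score
#' @param delta discount subtracted from the joint count (suppresses rare
#'   accidental co-occurrences)
#' @return object of class `shakespeare_vocabulary`: list with `terms`
#'   (ordered), `phrases`, `max_n`
#' @export
build_vocabulary <- function(documents, max_n = 5,
                             collocation_min_count = 5,
                             collocation_threshold = 10,
                             delta = 5) {
  if (length(documents) == 0) stopf("build_vocabulary: empty corpus")
  if (max_n < 1 || max_n > 5) stopf("max_n must be in 1..5")
  toks <- .tokenize(documents)
  if (sum(lengths(toks)) == 0) stopf("build_vocabulary: corpus has no tokens")
  unigrams <- unique(unlist(toks, use.names = FALSE))
  phrases <- character()
  units <- toks
  if (max_n > 1) {
    for (pass in seq_len(max_n - 1L)) {
      all_units <- unlist(units, use.names = FALSE)
      n_total <- length(all_units)
      ucount <- table(all_units)
      pairs <- unlist(lapply(units, function(u) {
        if (length(u) < 2) return(character())
        paste(u[-length(u)], u[-1])
      }), use.names = FALSE)
      if (length(pairs) == 0) break
      pcount <- table(pairs)
      cand <- names(pcount)[pcount >= collocation_min_count]
      if (length(cand) == 0) break
      keep <- vapply(cand, function(p) {
        ab <- pcount[[p]]
        sp <- strsplit(p, " ", fixed = TRUE)[[1]]
        # split back into the left/right units that formed the pair: the
        # merge below only ever joins existing units, so try all cut points
        best <- -Inf
        for (cut in seq_len(length(sp) - 1L)) {
          a <- paste(sp[seq_len(cut)], collapse = " ")
          b <- paste(sp[-seq_len(cut)], collapse = " ")
          ca <- ucount[a]; cb <- ucount[b]
          if (is.na(ca) || is.na(cb)) next
          best <- max(best, (ab - delta) * n_total / (as.numeric(ca) * as.numeric(cb)))
        }
        length(sp) <= max_n && best > collocation_threshold
      }, logical(1))
      admitted <- cand[keep]
      if (length(admitted) == 0) break
      phrases <- union(phrases, admitted)
      admit_env <- new.env(parent = emptyenv())
      for (p in admitted) assign(p, TRUE, envir = admit_env)
      units <- lapply(units, function(u) {
        n <- length(u)
        if (n < 2) return(u)
        out <- character(0)
        i <- 1L
        while (i <= n) {
          if (i < n && exists(paste(u[i], u[i + 1L]), envir = admit_env,
                              inherits = FALSE)) {
            out <- c(out, paste(u[i], u[i + 1L]))
            i <- i + 2L
          } else {
            out <- c(out, u[i])
            i <- i + 1L
          }
        }
        out
      })
    }
    phrases <- phrases[.n_words(phrases) <= max_n]
  }
  structure(list(terms = sort_terms(unique(c(unigrams, phrases))),
                 phrases = sort_terms(phrases),
                 max_n = as.integer(max_n)),
            class = "shakespeare_vocabulary")
}

#' @export
print.shakespeare_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d terms (%d multiword), max_n=%d>\n",
              length(x$terms), length(x$phrases), x$max_n))
  invisible(x)
}

#' Vectorize documents against a vocabulary
#'
#' Entry (i, j) is the count of term j in document i. Phrase occurrences
#' are counted by greedy left-to-right longest match; by default tokens
#' absorbed into a matched phrase are not additionally counted as their
#' component unigrams (`count_nested = TRUE` restores component counting).
#' Out-of-vocabulary tokens contribute nothing.
#'
#' @param documents character vector of normalized texts (names become
#'   document ids) or a data frame with `admission_id` and `text` columns
#' @param vocabulary a `shakespeare_vocabulary`, or a character vector of
#'   terms
#' @param count_nested also count unigrams inside matched phrases
#' @return object of class `term_matrix`: list with `counts` (sparse
#'   document x term integer matrix) and `terms`
#' @export
vectorize_documents <- function(documents, vocabulary, count_nested = FALSE) {
  if (is.data.frame(documents)) {
    documents <- setNames(documents$text, documents$admission_id)
  }
  terms <- if (inherits(vocabulary, "shakespeare_vocabulary")) {
    vocabulary$terms
  } else as.character(vocabulary)
  if (length(terms) == 0) stopf("vectorize_documents: empty vocabulary")
  doc_ids <- names(documents) %||% as.character(seq_along(documents))
  if (is.null(names(documents))) names(documents) <- doc_ids

  idx <- new.env(parent = emptyenv())
  for (k in seq_along(terms)) assign(terms[k], k, envir = idx)
  wl <- .n_words(terms)
  max_len <- max(wl)
  phrase_first <- unique(vapply(strsplit(terms[wl > 1], " ", fixed = TRUE),
                                `[`, character(1), 1L))

  toks <- .tokenize(documents)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(toks)) {
    t <- toks[[d]]
    n <- length(t)
    if (n == 0) next
    cols <- integer(0)
    i <- 1L
    while (i <= n) {
      matched <- 0L
      if (max_len > 1 && n - i + 1L >= 2L && t[i] %in% phrase_first) {
        for (len in seq(min(max_len, n - i + 1L), 2L)) {
          key <- paste(t[i:(i + len - 1L)], collapse = " ")
          j <- get0(key, envir = idx, inherits = FALSE)
          if (!is.null(j)) {
            cols <- c(cols, j)
            if (count_nested) {
              for (w in t[i:(i + len - 1L)]) {
                ju <- get0(w, envir = idx, inherits = FALSE)
                if (!is.null(ju)) cols <- c(cols, ju)
              }
            }
            matched <- len
            break
          }
        }
      }
      if (matched > 0L) {
        i <- i + matched
      } else {
        j <- get0(t[i], envir = idx, inherits = FALSE)
        if (!is.null(j)) cols <- c(cols, j)
        i <- i + 1L
      }
    }
    if (length(cols)) {
      tab <- tabulate(cols, nbins = length(terms))
      nz <- which(tab > 0L)
      ii <- c(ii, rep.int(d, length(nz)))
      jj <- c(jj, nz)
      xx <- c(xx, tab[nz])
    }
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(toks), length(terms)),
                                 dimnames = list(doc_ids, terms))
  structure(list(counts = counts, terms = terms), class = "term_matrix")
}

#' @export
print.term_matrix <- function(x, ...) {
  cat(sprintf("<term_matrix: %d documents x %d terms, %d nonzero>\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Write a term matrix as MatrixMarket + vocabulary text file
#' @param tm a `term_matrix`
#' @param mtx_path output .mtx path; the vocabulary is written next to it
#'   with extension .vocab.txt and document ids with .docs.txt
#' @return invisibly, the paths written
#' @export
write_term_matrix <- function(tm, mtx_path) {
  Matrix::writeMM(tm$counts, mtx_path)
  vocab_path <- sub("\\.mtx$", "", mtx_path)
  writeLines(tm$terms, paste0(vocab_path, ".vocab.txt"))
  writeLines(rownames(tm$counts), paste0(vocab_path, ".docs.txt"))
  invisible(c(mtx_path, paste0(vocab_path, ".vocab.txt"),
              paste0(vocab_path, ".docs.txt")))
}

#' Read a term matrix written by [write_term_matrix()]
#' @param mtx_path the .mtx path
#' @return a `term_matrix`
#' @export
read_term_matrix <- function(mtx_path) {
  m <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
  base <- sub("\\.mtx$", "", mtx_path)
  terms <- readLines(paste0(base, ".vocab.txt"))
  docs <- readLines(paste0(base, ".docs.txt"))
  dimnames(m) <- list(docs, terms)
  structure(list(counts = m, terms = terms), class = "term_matrix")
}
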
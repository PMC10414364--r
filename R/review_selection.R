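# Choosing the documents a human reviewer reads: the top-k documents per
# topic, the documents spread across the most topics, and an independent
# random sample, plus the max-topic cross-table used to characterize the
# corpus.

#' Select the manual-review document set
#'
#' For each topic, the `top_k` documents by that topic's score (ties broken
#' by ascending document id); the `n_multi` documents with the most topics
#' at or above `sig_threshold` (strict count order); and `n_random`
#' documents sampled uniformly without replacement. The random sample is
#' drawn independently and may overlap the other lists.
#'
#' @param doc_topic D x K document-topic probability matrix (row names are
#'   document ids)
#' @param top_k documents per topic
#' @param sig_threshold significant-score threshold (default 0.03)
#' @param n_multi number of multi-topic documents
#' @param n_random size of the random sample
#' @param seed RNG seed for the random sample
#' @param exclude_ids optional document ids the random sampler must avoid
#'   (stands in for manual clinical exclusions)
#' @return list of class `review_set`: `per_topic` (data frame topic /
#'   rank / document / score), `multi_topic` (data frame document /
#'   n_topics), `random` (document ids), `params`
#' @export
select_review_set <- function(doc_topic, top_k = 3, sig_threshold = 0.03,
                              n_multi = 7, n_random = 24, seed = 1L,
                              exclude_ids = NULL) {
  stopifnot(is.matrix(doc_topic), top_k >= 1,
            sig_threshold > 0, sig_threshold < 1)
  D <- nrow(doc_topic); K <- ncol(doc_topic)
  ids <- rownames(doc_topic) %||% as.character(seq_len(D))
  if (n_random > D) stopf("n_random (%d) exceeds document count (%d)", n_random, D)

  per_topic <- do.call(rbind, lapply(seq_len(K), function(k) {
    ord <- order(-doc_topic[, k], ids, method = "radix")[seq_len(min(top_k, D))]
    data.frame(topic = k, rank = seq_along(ord), document = ids[ord],
               score = doc_topic[ord, k], stringsAsFactors = FALSE)
  }))
  rownames(per_topic) <- NULL

  n_topics <- rowSums(doc_topic >= sig_threshold)
  ord <- order(-n_topics, ids, method = "radix")[seq_len(min(n_multi, D))]
  multi_topic <- data.frame(document = ids[ord], n_topics = n_topics[ord],
                            stringsAsFactors = FALSE)
  rownames(multi_topic) <- NULL

  pool <- setdiff(ids, exclude_ids)
  if (n_random > length(pool)) {
    stopf("n_random exceeds the non-excluded document count")
  }
  random_ids <- with_seed(seed, sample(pool, n_random))

  structure(list(per_topic = per_topic, multi_topic = multi_topic,
                 random = random_ids,
                 params = list(top_k = top_k, sig_threshold = sig_threshold,
                               n_multi = n_multi, n_random = n_random,
                               seed = as.integer(seed))),
            class = "review_set")
}

#' @export
print.review_set <- function(x, ...) {
  cat(sprintf("<review_set: %d per-topic rows, %d multi-topic, %d random>\n",
              nrow(x$per_topic), nrow(x$multi_topic), length(x$random)))
  invisible(x)
}

#' Cross-table of topic multiplicity by maximum document score
#'
#' Rows are the number of topics with score >= `sig_threshold` in a
#' document (0 .. K); columns are bands of the document's maximum topic
#' score (>= bands\[1\], then half-open intervals down to a final
#' below-all-bands column), so every document falls in exactly one cell
#' and each column-wise total equals the document count. Also returns the
#' per-document maximum-score vector (the max-topic histogram data).
#'
#' @param doc_topic D x K document-topic probability matrix
#' @param sig_threshold significant-score threshold
#' @param bands descending maximum-score cut points
#' @return list of class `max_topic_table`: `table` (matrix), `max_scores`
#' @export
max_topic_table <- function(doc_topic, sig_threshold = 0.03,
                            bands = c(0.5, 0.2, 0.1)) {
  stopifnot(is.matrix(doc_topic), sig_threshold > 0, sig_threshold < 1)
  if (is.unsorted(rev(bands))) stopf("bands must be strictly decreasing")
  K <- ncol(doc_topic)
  n_topics <- rowSums(doc_topic >= sig_threshold)
  max_score <- apply(doc_topic, 1, max)
  breaks <- c(Inf, bands, -Inf)
  band_idx <- cut(max_score, breaks = rev(breaks), right = FALSE,
                  labels = FALSE)
  band_idx <- length(breaks) - band_idx  # 1 = top band
  upper <- c(Inf, bands)
  labels <- c(paste0(">=", bands[1]),
              if (length(bands) > 1)
                paste0("[", bands[-1], ",", bands[-length(bands)], ")"),
              paste0("<", bands[length(bands)]))
  tab <- matrix(0L, nrow = K + 1L, ncol = length(labels),
                dimnames = list(0:K, labels))
  for (d in seq_along(n_topics)) {
    tab[n_topics[d] + 1L, band_idx[d]] <- tab[n_topics[d] + 1L, band_idx[d]] + 1L
  }
  structure(list(table = tab, max_scores = max_score,
                 sig_threshold = sig_threshold, bands = bands),
            class = "max_topic_table")
}

#' @export
print.max_topic_table <- function(x, ...) {
  cat(sprintf("<max_topic_table: threshold %.2f>\n", x$sig_threshold))
  nz <- rowSums(x$table) > 0
  print(x$table[nz, , drop = FALSE])
  invisible(x)
}
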
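# Latent Dirichlet allocation by batch variational Bayes.
#
# Symmetric Dirichlet priors (alpha = eta = 1/K by default), mean-field
# variational inference with the standard per-document fixed-point E-step
# and a batch M-step. Variational inference is used (rather than collapsed
# Gibbs) for exact determinism under a fixed seed. A document with zero
# in-vocabulary terms keeps its variational posterior at the prior, so its
# topic distribution is exactly uniform (1/K per topic).

#' Fit an LDA topic model
#'
#' @param tm a `term_matrix` (documents x terms, nonnegative counts)
#' @param K number of topics (>= 2; at most the number of documents)
#' @param seed RNG seed for the topic-term initialization
#' @param alpha symmetric document-topic Dirichlet prior (default `1/K`)
#' @param eta symmetric topic-term Dirichlet prior (default `1/K`)
#' @param max_iter maximum corpus passes
#' @param tol convergence tolerance on the mean absolute change of the
#'   document-topic posterior between passes
#' @return object of class `lda_result`: `doc_topic` (D x K rows summing
#'   to 1), `term_topic` (K x V expected pseudo-count "term scores"),
#'   `beta` (normalized topic-term probabilities), `K`, hyperparameters,
#'   `seed`, `n_iter`
#' @export
fit_lda <- function(tm, K, seed = 1L, alpha = NULL, eta = NULL,
                    max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(tm, "term_matrix"))
  X <- tm$counts
  D <- nrow(X); V <- ncol(X)
  if (K < 2) stopf("fit_lda: K must be >= 2")
  if (D == 0 || V == 0) stopf("fit_lda: empty matrix")
  if (D < K) stopf("fit_lda: need at least K documents (D=%d, K=%d)", D, K)
  alpha <- alpha %||% (1 / K)
  eta <- eta %||% (1 / K)

  lambda <- with_seed(seed, matrix(rgamma(K * V, shape = 100, rate = 100), K, V))
  Xc <- as(X, "RsparseMatrix")  # row-oriented: fast per-document access
  doc_ids <- lapply(seq_len(D), function(d) {
    if (Xc@p[d] == Xc@p[d + 1L]) integer(0)
    else Xc@j[(Xc@p[d] + 1L):Xc@p[d + 1L]] + 1L
  })
  doc_cts <- lapply(seq_len(D), function(d) {
    if (Xc@p[d] == Xc@p[d + 1L]) numeric(0)
    else Xc@x[(Xc@p[d] + 1L):Xc@p[d + 1L]]
  })
  n_d <- vapply(doc_cts, sum, numeric(1))

  gamma_mat <- matrix(alpha, D, K) + n_d / K
  gamma_mat[n_d == 0, ] <- alpha          # empty docs stay at the prior
  prev_gamma <- gamma_mat
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
    expElogbeta <- exp(Elogbeta)
    sstats <- matrix(0, K, V)
    for (d in seq_len(D)) {
      ids <- doc_ids[[d]]
      if (length(ids) == 0) next
      cts <- doc_cts[[d]]
      gamma_d <- alpha + n_d[d] / K + numeric(K)
      expElogtheta <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
      eb <- expElogbeta[, ids, drop = FALSE]
      for (it in seq_len(100L)) {
        phinorm <- as.numeric(crossprod(eb, expElogtheta)) + 1e-100
        gamma_new <- alpha + expElogtheta * as.numeric(eb %*% (cts / phinorm))
        if (mean(abs(gamma_new - gamma_d)) < 1e-3) { gamma_d <- gamma_new; break }
        gamma_d <- gamma_new
        expElogtheta <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
      }
      expElogtheta <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
      phinorm <- as.numeric(crossprod(eb, expElogtheta)) + 1e-100
      sstats[, ids] <- sstats[, ids] +
        outer(expElogtheta, cts / phinorm) * eb
      gamma_mat[d, ] <- gamma_d
    }
    lambda <- eta + sstats
    delta <- mean(abs(gamma_mat - prev_gamma))
    prev_gamma <- gamma_mat
    if (delta < tol) break
  }

  doc_topic <- gamma_mat / rowSums(gamma_mat)
  dimnames(doc_topic) <- list(rownames(X), paste0("topic", seq_len(K)))
  term_topic <- lambda - eta            # expected topic-term pseudo-counts
  dimnames(term_topic) <- list(paste0("topic", seq_len(K)), colnames(X))
  beta <- lambda / rowSums(lambda)
  dimnames(beta) <- dimnames(term_topic)
  structure(list(K = as.integer(K), doc_topic = doc_topic,
                 term_topic = term_topic, beta = beta,
                 alpha = alpha, eta = eta, seed = as.integer(seed),
                 n_iter = n_iter, terms = tm$terms),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("<lda_result: K=%d, %d documents, %d terms, %d passes>\n",
              x$K, nrow(x$doc_topic), ncol(x$term_topic), x$n_iter))
  invisible(x)
}

#' Fit LDA models over a grid of topic counts
#'
#' One fitted model per K plus the tuning diagnostics used to judge a
#' topic count: how many topics have a top document score of at least 0.5
#' ("coherent" in this method's usage), how many are weak (top document
#' score < 0.1), and the mean number of topics per document at the
#' significant-score threshold.
#'
#' @param tm a `term_matrix`
#' @param K_list integer vector of topic counts
#' @param seed RNG seed (shared across fits)
#' @param sig_threshold document-topic score that counts a topic as present
#'   in a document (default 0.03)
#' @param ... passed to [fit_lda()]
#' @return list of class `lda_tuning`; per K: `K`, `model`, `diagnostics`
#' @export
tune_k <- function(tm, K_list, seed = 1L, sig_threshold = 0.03, ...) {
  if (length(K_list) == 0) stopf("tune_k: K_list must be non-empty")
  out <- lapply(K_list, function(K) {
    model <- fit_lda(tm, K = K, seed = seed, ...)
    top_doc <- apply(model$doc_topic, 2, max)
    diag <- c(coherent_topics = sum(top_doc >= 0.5),
              weak_topics = sum(top_doc < 0.1),
              mean_topics_per_doc =
                mean(rowSums(model$doc_topic >= sig_threshold)))
    list(K = as.integer(K), model = model, diagnostics = diag)
  })
  class(out) <- "lda_tuning"
  out
}

#' Summarize a fitted topic model
#'
#' Per topic: the top term score, the `top_n` highest-scoring terms, the
#' top document score, and the count of documents falling in each
#' document-score band. The default bands are >=0.5, \[0.2, 0.5),
#' \[0.1, 0.2) and \[0.03, 0.1); rows are sorted by top document score,
#' descending.
#'
#' @param result an `lda_result`
#' @param top_n terms listed per topic
#' @param bands descending score cut points; band i counts documents with
#'   `bands[i] <= score < bands[i-1]` (the first band is unbounded above)
#' @return data frame of class `topic_summary`
#' @export
summarize_topics <- function(result, top_n = 20,
                             bands = c(0.5, 0.2, 0.1, 0.03)) {
  stopifnot(inherits(result, "lda_result"))
  if (top_n > ncol(result$term_topic)) stopf("top_n exceeds vocabulary size")
  if (is.unsorted(rev(bands))) stopf("bands must be strictly decreasing")
  K <- result$K
  terms <- colnames(result$term_topic)
  rows <- lapply(seq_len(K), function(k) {
    sc <- result$term_topic[k, ]
    ord <- order(-sc, terms, method = "radix")[seq_len(top_n)]
    ds <- result$doc_topic[, k]
    upper <- c(Inf, bands[-length(bands)])
    counts <- vapply(seq_along(bands),
                     function(i) sum(ds >= bands[i] & ds < upper[i]),
                     numeric(1))
    names(counts) <- paste0("n_", bands)
    cbind(data.frame(topic = k,
                     top_term_score = unname(sc[ord[1]]),
                     top_terms = paste(terms[ord], collapse = ", "),
                     top_doc_score = max(ds),
                     n_sig = sum(ds >= bands[length(bands)]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$top_doc_score, out$topic), ]
  rownames(out) <- NULL
  class(out) <- c("topic_summary", "data.frame")
  out
}
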
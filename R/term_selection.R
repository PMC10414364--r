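# Selection of terms statistically significant for the target group.
#
# Two strategies, matching the two surveillance designs:
#  * ensemble   — target vs. comparison admissions: union of top logistic
#                 regression coefficients, top naive Bayes log-probability
#                 ratios, and target-exclusive terms, so that common,
#                 infrequent and rare target-significant terms are all kept;
#  * temporal   — recent period vs. prior period: intersection of a
#                 classification set (top-k LR union top-k NB) with a
#                 frequency set (<10% prevalence terms whose raw count rose
#                 >=30%, plus brand-new non-digit terms).

.check_shared_vocab <- function(a, b) {
  stopifnot(inherits(a, "term_matrix"), inherits(b, "term_matrix"))
  if (!identical(a$terms, b$terms)) {
    stopf("term matrices must share one vocabulary")
  }
}

# multinomial NB per-term log probability ratio with Laplace smoothing:
# log P(term | reference class) - log P(term | target class).
# The lowest (most negative) values are the most target-favoring.
.nb_log_ratio <- function(target_counts, reference_counts, alpha = 1) {
  V <- length(target_counts)
  lt <- log(target_counts + alpha) - log(sum(target_counts) + alpha * V)
  lr <- log(reference_counts + alpha) - log(sum(reference_counts) + alpha * V)
  lr - lt
}

# ridge logistic regression coefficients for target (y=1) vs reference (y=0)
.lr_coefficients <- function(x, y, lambda = NULL) {
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  drop(as.matrix(coef(fit)))[-1]
}

.rank_top <- function(terms, score, k, decreasing = TRUE) {
  ord <- if (decreasing) order(-score, terms, method = "radix")
         else order(score, terms, method = "radix")
  terms[ord][seq_len(min(k, length(terms)))]
}

#' Select target-significant terms with the classifier ensemble
#'
#' Fits ridge logistic regression and multinomial naive Bayes to label
#' target vs. comparison documents, then takes the union of (a) the top
#' `k_lr` terms by positive LR coefficient, (b) the top `k_nb` terms by
#' lowest NB log-probability ratio, and (c) target-exclusive terms with
#' corpus count at least `exclusive_min_count`. `margin` excludes terms
#' without strictly positive discriminative evidence (LR coefficient must
#' exceed `margin`; NB ratio must fall below `-margin`), so identical
#' groups select nothing.
#'
#' @param target,comparison `term_matrix` objects over one shared vocabulary
#' @param k_lr,k_nb list sizes for the two classifier rankings
#' @param exclusive_min_count minimum target count for comparison-absent terms
#' @param margin nonnegative evidence margin
#' @param alpha Laplace smoothing for NB
#' @param lambda ridge penalty for LR (default `1/n`)
#' @return object of class `term_selection_result`: `selected` (sorted
#'   term set), `diagnostics` (per-term scores, frequencies, path flags),
#'   `stage_counts`
#' @export
select_terms_ensemble <- function(target, comparison,
                                  k_lr = 20000, k_nb = 20000,
                                  exclusive_min_count = 3,
                                  margin = 0, alpha = 1, lambda = NULL) {
  .check_shared_vocab(target, comparison)
  if (nrow(target$counts) == 0 || nrow(comparison$counts) == 0) {
    stopf("select_terms_ensemble: both groups must be non-empty")
  }
  terms <- target$terms
  ct <- Matrix::colSums(target$counts)
  cc <- Matrix::colSums(comparison$counts)
  dft <- Matrix::colSums(target$counts > 0)
  dfc <- Matrix::colSums(comparison$counts > 0)

  x <- rbind(target$counts, comparison$counts)
  y <- c(rep(1L, nrow(target$counts)), rep(0L, nrow(comparison$counts)))
  lr_coef <- .lr_coefficients(x, y, lambda)
  nb_ratio <- .nb_log_ratio(ct, cc, alpha)

  lr_pool <- terms[lr_coef > margin]
  lr_set <- .rank_top(lr_pool, lr_coef[lr_coef > margin], k_lr, decreasing = TRUE)
  nb_pool <- terms[nb_ratio < -margin]
  nb_set <- .rank_top(nb_pool, nb_ratio[nb_ratio < -margin], k_nb, decreasing = FALSE)
  excl_set <- terms[cc == 0 & ct >= exclusive_min_count]

  selected <- sort_terms(unique(c(lr_set, nb_set, excl_set)))
  diagnostics <- data.frame(
    term = terms,
    lr_coef = unname(lr_coef),
    nb_log_ratio = unname(nb_ratio),
    doc_freq_target = unname(dft),
    doc_freq_comparison = unname(dfc),
    count_target = unname(ct),
    count_comparison = unname(cc),
    path_lr = terms %in% lr_set,
    path_nb = terms %in% nb_set,
    path_exclusive = terms %in% excl_set,
    stringsAsFactors = FALSE
  )
  diagnostics$selected <- diagnostics$path_lr | diagnostics$path_nb |
    diagnostics$path_exclusive
  structure(list(
    strategy = "ensemble",
    selected = selected,
    diagnostics = diagnostics,
    stage_counts = c(vocabulary = length(terms),
                     lr_top = length(lr_set), nb_top = length(nb_set),
                     target_exclusive = length(excl_set),
                     selected = length(selected))
  ), class = "term_selection_result")
}

#' Select terms for a recent period vs. a prior period
#'
#' Classification set: both models are fit on all documents of the two
#' periods (no train/test split; recent period is the positive class); the
#' top `k_lr` terms with highest positive LR coefficients are united with
#' the `k_nb` terms with the lowest NB log-probability ratios. Frequency
#' set: terms present in fewer than `low_prevalence` of prior-period
#' documents whose raw corpus count grew by at least `increase` in the
#' recent period, united with terms absent from the prior period that
#' appear in the recent period (digit-only new terms are filtered out).
#' The selection is the intersection of the two sets.
#'
#' @param period2,period3 prior- and recent-period `term_matrix` objects
#'   sharing one vocabulary built on their union
#' @param k_lr,k_nb classifier list sizes
#' @param low_prevalence document-frequency ceiling in the prior period
#' @param increase required relative raw-count increase (0.30 = +30%)
#' @param normalize_frequency compare per-document-normalized counts
#'   instead of raw corpus counts
#' @param alpha,lambda model hyperparameters as in [select_terms_ensemble()]
#' @return a `term_selection_result`; `sets` carries the intermediate
#'   classification and frequency sets
#' @export
select_terms_temporal <- function(period2, period3,
                                  k_lr = 5000, k_nb = 5000,
                                  low_prevalence = 0.10, increase = 0.30,
                                  normalize_frequency = FALSE,
                                  alpha = 1, lambda = NULL) {
  .check_shared_vocab(period2, period3)
  n2 <- nrow(period2$counts); n3 <- nrow(period3$counts)
  if (n2 == 0 || n3 == 0) stopf("select_terms_temporal: empty period")
  terms <- period2$terms
  c2 <- Matrix::colSums(period2$counts)
  c3 <- Matrix::colSums(period3$counts)
  df2 <- Matrix::colSums(period2$counts > 0)
  df3 <- Matrix::colSums(period3$counts > 0)

  x <- rbind(period2$counts, period3$counts)
  y <- c(rep(0L, n2), rep(1L, n3))
  lr_coef <- .lr_coefficients(x, y, lambda)
  nb_ratio <- .nb_log_ratio(c3, c2, alpha)

  lr_set <- .rank_top(terms[lr_coef > 0], lr_coef[lr_coef > 0], k_lr,
                      decreasing = TRUE)
  nb_set <- .rank_top(terms, nb_ratio, k_nb, decreasing = FALSE)
  classification <- unique(c(lr_set, nb_set))

  f2 <- if (normalize_frequency) c2 / n2 else c2
  f3 <- if (normalize_frequency) c3 / n3 else c3
  increased <- terms[c2 > 0 & df2 / n2 < low_prevalence &
                       f3 >= (1 + increase) * f2]
  new_terms <- terms[c2 == 0 & c3 > 0]
  new_terms <- new_terms[!is_digit_only(new_terms)]
  frequency <- unique(c(increased, new_terms))

  selected <- sort_terms(intersect(classification, frequency))
  diagnostics <- data.frame(
    term = terms,
    lr_coef = unname(lr_coef),
    nb_log_ratio = unname(nb_ratio),
    doc_freq_period2 = unname(df2),
    doc_freq_period3 = unname(df3),
    count_period2 = unname(c2),
    count_period3 = unname(c3),
    path_classification = terms %in% classification,
    path_frequency_increase = terms %in% increased,
    path_new_term = terms %in% new_terms,
    stringsAsFactors = FALSE
  )
  diagnostics$selected <- terms %in% selected
  structure(list(
    strategy = "temporal",
    selected = selected,
    diagnostics = diagnostics,
    sets = list(lr = lr_set, nb = nb_set, classification = classification,
                frequency_increase = increased, new_terms = new_terms,
                frequency = frequency),
    stage_counts = c(vocabulary = length(terms),
                     lr_top = length(lr_set), nb_top = length(nb_set),
                     classification = length(classification),
                     frequency = length(frequency),
                     selected = length(selected))
  ), class = "term_selection_result")
}

#' @export
print.term_selection_result <- function(x, ...) {
  cat(sprintf("<term_selection_result (%s): %d terms selected>\n",
              x$strategy, length(x$selected)))
  print(x$stage_counts)
  invisible(x)
}

#' Evaluate the two classifiers on a held-out split
#'
#' Stratified split of the two periods, then ridge logistic regression and
#' multinomial naive Bayes are fit on the training part and scored on the
#' held-out part with the weighted-average F1 (weights = class support).
#'
#' @param period2,period3 `term_matrix` objects sharing a vocabulary
#' @param split_fraction held-out fraction per class
#' @param seed RNG seed for the split
#' @param alpha,lambda model hyperparameters
#' @return list of class `classifier_eval`: weighted F1 and per-class
#'   precision/recall for each model, plus split parameters
#' @export
evaluate_classifiers <- function(period2, period3, split_fraction = 0.25,
                                 seed = 1L, alpha = 1, lambda = NULL) {
  .check_shared_vocab(period2, period3)
  n2 <- nrow(period2$counts); n3 <- nrow(period3$counts)
  if (n2 == 0 || n3 == 0) stopf("evaluate_classifiers: empty period")
  t2 <- max(1L, round(split_fraction * n2))
  t3 <- max(1L, round(split_fraction * n3))
  if (t2 >= n2 || t3 >= n3) stopf("degenerate split: no training documents left")
  test_idx <- with_seed(seed, list(p2 = sample.int(n2, t2),
                                   p3 = sample.int(n3, t3)))
  xtr <- rbind(period2$counts[-test_idx$p2, , drop = FALSE],
               period3$counts[-test_idx$p3, , drop = FALSE])
  ytr <- c(rep(0L, n2 - t2), rep(1L, n3 - t3))
  xte <- rbind(period2$counts[test_idx$p2, , drop = FALSE],
               period3$counts[test_idx$p3, , drop = FALSE])
  yte <- c(rep(0L, t2), rep(1L, t3))

  lr_coef <- NULL
  if (is.null(lambda)) lambda <- 1 / nrow(xtr)
  lr_fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                           lambda = lambda, standardize = FALSE)
  lr_pred <- as.integer(predict(lr_fit, xte, type = "response") > 0.5)

  # multinomial NB: class log priors + counts . log term probabilities
  V <- ncol(xtr)
  log_p1 <- log(Matrix::colSums(xtr[ytr == 1, , drop = FALSE]) + alpha) -
    log(sum(xtr[ytr == 1, ]) + alpha * V)
  log_p0 <- log(Matrix::colSums(xtr[ytr == 0, , drop = FALSE]) + alpha) -
    log(sum(xtr[ytr == 0, ]) + alpha * V)
  prior1 <- log(mean(ytr == 1)); prior0 <- log(mean(ytr == 0))
  s1 <- prior1 + as.numeric(xte %*% log_p1)
  s0 <- prior0 + as.numeric(xte %*% log_p0)
  nb_pred <- as.integer(s1 > s0)

  per_class <- function(pred) {
    do.call(rbind, lapply(c(0L, 1L), function(cl) {
      tp <- sum(yte == cl & pred == cl)
      data.frame(class = cl,
                 precision = if (sum(pred == cl)) tp / sum(pred == cl) else NA_real_,
                 recall = tp / sum(yte == cl))
    }))
  }
  structure(list(
    lr = list(weighted_f1 = weighted_f1(yte, lr_pred), by_class = per_class(lr_pred)),
    nb = list(weighted_f1 = weighted_f1(yte, nb_pred), by_class = per_class(nb_pred)),
    split_fraction = split_fraction,
    n_test = c(period2 = t2, period3 = t3),
    seed = as.integer(seed)
  ), class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval: LR weighted F1 %.3f, NB weighted F1 %.3f>\n",
              x$lr$weighted_f1, x$nb$weighted_f1))
  invisible(x)
}

#' Restrict a term matrix to a selected term set
#'
#' Columns are restricted to `selected` (counts unchanged), the vector-
#' trimming step applied to the target-group documents before topic
#' modeling.
#'
#' @param tm a `term_matrix`
#' @param selected character vector, a subset of the vocabulary
#' @return a `term_matrix` over the selected terms (vocabulary order
#'   preserved)
#' @export
trim_matrix <- function(tm, selected) {
  stopifnot(inherits(tm, "term_matrix"))
  if (length(selected) == 0) stopf("trim_matrix: empty term selection")
  extra <- setdiff(selected, tm$terms)
  if (length(extra)) {
    stopf("trim_matrix: term(s) not in vocabulary: %s",
          paste(head(extra, 5), collapse = ", "))
  }
  keep <- tm$terms %in% selected
  structure(list(counts = tm$counts[, keep, drop = FALSE],
                 terms = tm$terms[keep]),
            class = "term_matrix")
}
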
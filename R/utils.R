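#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix colSums rowSums readMM writeMM Matrix
#' @importFrom methods as
#' @importFrom stats lm confint coef predict residuals dhyper runif rgamma
#'   setNames var
#' @importFrom utils read.csv write.csv write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stopf("configuration error: %s must be a probability in [0, 1]", name)
  }
  invisible(x)
}

# C-locale lexicographic sort, stable and platform independent
sort_terms <- function(x) sort(x, method = "radix")

# digit-only filter: TRUE when every whitespace token of the term is all digits
is_digit_only <- function(terms) {
  vapply(strsplit(terms, " ", fixed = TRUE),
         function(tok) length(tok) > 0 && all(grepl("^[0-9]+$", tok)),
         logical(1))
}

# weighted-average F1 over classes (weights = class support in `truth`)
weighted_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}
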
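# Quarterly surveillance statistics and the group-comparison Fisher test.
#
# A presence criterion is a small boolean expression over word-presence
# atoms (whole-token match in the document text, '*' allows any suffix),
# code-presence atoms (against the admission's code list, '*' allowed),
# and stay-length predicates. Per calendar quarter the proportion of
# admissions satisfying the criterion is computed, and an unweighted OLS
# line of proportion on quarter index gives the slope, its 95% CI and the
# p-value reported in surveillance plots.

# ---- criterion parsing -----------------------------------------------------

.tokenize_criterion <- function(text) {
  pat <- paste0(
    '(word:"[^"]*")|(code:"[^"]*")|',
    '(stay\\s*(>=|<=|>|<)\\s*[0-9]+)|',
    "(\\()|(\\))|(AND)|(OR)|(NOT)"
  )
  m <- gregexpr(pat, text, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) stopf("criterion parse error: no tokens in %s", text)
  toks <- regmatches(text, list(m))[[1]]
  leftover <- trimws(gsub(pat, " ", text, ignore.case = TRUE))
  if (nzchar(leftover)) {
    stopf("criterion parse error: unexpected input '%s'", leftover)
  }
  toks
}

#' Parse a presence criterion
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := NOT factor | '(' expr ')' | atom`, with atoms
#' `word:"heparin"`, `word:"occlusion*"`, `code:"38.*"` and stay-length
#' predicates such as `stay>=14` (days).
#'
#' @param text criterion expression
#' @return object of class `presence_criterion`
#' @export
parse_criterion <- function(text) {
  toks <- .tokenize_criterion(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      advance()
      node <- list(op = "or", left = node, right = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      advance()
      node <- list(op = "and", left = node, right = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stopf("criterion parse error: unexpected end of input")
    if (toupper(t) == "NOT") {
      advance()
      return(list(op = "not", arg = parse_factor()))
    }
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") stopf("criterion parse error: missing ')'")
      advance()
      return(node)
    }
    advance()
    if (grepl('^word:"', t, ignore.case = TRUE)) {
      return(list(op = "word", value = tolower(sub('^word:"(.*)"$', "\\1", t,
                                                   ignore.case = TRUE))))
    }
    if (grepl('^code:"', t, ignore.case = TRUE)) {
      return(list(op = "code", value = sub('^code:"(.*)"$', "\\1", t,
                                           ignore.case = TRUE)))
    }
    if (grepl("^stay", t, ignore.case = TRUE)) {
      cmp <- sub("^stay\\s*(>=|<=|>|<)\\s*[0-9]+$", "\\1", t, ignore.case = TRUE)
      n <- as.numeric(sub("^stay\\s*(>=|<=|>|<)\\s*([0-9]+)$", "\\2", t,
                          ignore.case = TRUE))
      return(list(op = "stay", cmp = cmp, value = n))
    }
    stopf("criterion parse error: unexpected token '%s'", t)
  }
  node <- parse_expr()
  if (pos <= length(toks)) {
    stopf("criterion parse error: trailing input from '%s'", toks[pos])
  }
  structure(node, class = "presence_criterion")
}

.match_values <- function(values, pattern) {
  if (endsWith(pattern, "*")) {
    any(startsWith(values, substr(pattern, 1L, nchar(pattern) - 1L)))
  } else {
    any(values == pattern)
  }
}

.eval_criterion <- function(node, tokens, codes, stay_days) {
  switch(node$op,
    and = .eval_criterion(node$left, tokens, codes, stay_days) &&
          .eval_criterion(node$right, tokens, codes, stay_days),
    or = .eval_criterion(node$left, tokens, codes, stay_days) ||
         .eval_criterion(node$right, tokens, codes, stay_days),
    not = !.eval_criterion(node$arg, tokens, codes, stay_days),
    word = .match_values(tokens, node$value),
    code = .match_values(codes, node$value),
    stay = switch(node$cmp,
                  ">=" = stay_days >= node$value,
                  "<=" = stay_days <= node$value,
                  ">" = stay_days > node$value,
                  "<" = stay_days < node$value),
    stopf("unknown criterion node '%s'", node$op)
  )
}

# document tokens for word matching: vectorizer normalization then
# leading/trailing punctuation stripped from each token
.criterion_tokens <- function(text, pii_mask = "[**PII**]") {
  toks <- .tokenize(normalize_text(text, pii_mask))[[1]]
  unique(gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks))
}

#' Evaluate a presence criterion for one admission
#'
#' @param criterion a [parse_criterion()] result
#' @param text the admission's (deduplicated) document text
#' @param codes character vector of the admission's diagnosis/procedure codes
#' @param stay_days length of stay in days
#' @return TRUE/FALSE
#' @export
evaluate_criterion <- function(criterion, text, codes = character(),
                               stay_days = 0) {
  stopifnot(inherits(criterion, "presence_criterion"))
  .eval_criterion(criterion, .criterion_tokens(text), codes, stay_days)
}

#' Load a named-criteria file
#'
#' One criterion per line as `name: expression`; blank lines and lines
#' starting with `#` are skipped.
#' @param path file path
#' @return named list of `presence_criterion` objects
#' @export
load_criteria <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  names_ <- sub(":.*$", "", lines)
  exprs <- sub("^[^:]*:", "", lines)
  setNames(lapply(exprs, parse_criterion), trimws(names_))
}

# ---- quarterly series ------------------------------------------------------

.quarter_start <- function(dates) {
  d <- as.POSIXlt(dates, tz = "UTC")
  as.Date(sprintf("%d-%02d-01", d$year + 1900L, (d$mon %/% 3L) * 3L + 1L))
}

#' Per-quarter proportions of admissions satisfying a criterion
#'
#' Admissions are assigned to the calendar quarter of their first note.
#' The numerator counts admissions satisfying the criterion; the
#' denominator counts all admissions in that quarter.
#'
#' @param documents data frame from [assemble_documents()] (columns
#'   `admission_id`, `text`, `first_charttime`; optional `stay_days`)
#' @param criterion a `presence_criterion` (or its expression string)
#' @param codes optional codes data frame (ADMISSION_ID, CODE_TYPE, CODE)
#' @param quarters optional Date vector of quarter starts covering all
#'   admissions; an admission outside all quarters is an error
#' @return object of class `trend_series`: data frame with `quarter`,
#'   `index`, `numerator`, `denominator`, `proportion`, plus a `fit`
#'   attribute filled by [fit_trend()]
#' @export
quarterly_proportions <- function(documents, criterion, codes = NULL,
                                  quarters = NULL) {
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  stopifnot(inherits(criterion, "presence_criterion"))
  adm_q <- .quarter_start(documents$first_charttime)
  if (is.null(quarters)) {
    quarters <- seq(min(adm_q), max(adm_q), by = "3 months")
  }
  quarters <- as.Date(quarters)
  outside <- !(adm_q %in% quarters)
  if (any(outside)) {
    stopf("admission(s) outside all quarters: %s",
          paste(head(documents$admission_id[outside], 5), collapse = ", "))
  }
  code_map <- if (!is.null(codes)) split(codes$CODE, codes$ADMISSION_ID) else list()
  stay <- documents$stay_days %||% rep(0, nrow(documents))
  hit <- vapply(seq_len(nrow(documents)), function(i) {
    .eval_criterion(criterion, .criterion_tokens(documents$text[i]),
                    code_map[[documents$admission_id[i]]] %||% character(),
                    stay[i])
  }, logical(1))
  num <- vapply(quarters, function(q) sum(hit[adm_q == q]), numeric(1))
  den <- vapply(quarters, function(q) sum(adm_q == q), numeric(1))
  df <- data.frame(quarter = quarters, index = seq_along(quarters),
                   numerator = num, denominator = den,
                   proportion = ifelse(den > 0, num / den, NA_real_))
  structure(list(series = df, fit = NULL), class = "trend_series")
}

#' Build a trend series directly from counts
#'
#' @param numerator,denominator per-quarter counts (numerator <= denominator)
#' @param quarters optional Date vector of quarter starts
#' @return a `trend_series`
#' @export
trend_series <- function(numerator, denominator, quarters = NULL) {
  stopifnot(length(numerator) == length(denominator),
            all(numerator >= 0), all(numerator <= denominator))
  q <- quarters %||% seq(as.Date("2001-07-01"), by = "3 months",
                         length.out = length(numerator))
  df <- data.frame(quarter = as.Date(q), index = seq_along(numerator),
                   numerator = numerator, denominator = denominator,
                   proportion = numerator / denominator)
  structure(list(series = df, fit = NULL), class = "trend_series")
}

#' Fit a linear trend to a quarterly proportion series
#'
#' Default: unweighted ordinary least squares of proportion on quarter
#' index, giving the slope per quarter, its two-sided confidence interval
#' and the p-value for slope = 0. A binomial-GLM alternative (logit scale)
#' is available with `method = "binomial"`.
#'
#' @param ts a `trend_series`
#' @param method `"ols"` or `"binomial"`
#' @param conf_level confidence level (default 0.95)
#' @return the `trend_series` with `fit` set: `slope`, `ci_lower`,
#'   `ci_upper`, `p_value`, `method`
#' @export
fit_trend <- function(ts, method = c("ols", "binomial"), conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "trend_series"))
  df <- ts$series
  if (nrow(df) < 3) stopf("fit_trend: need at least 3 quarters")
  if (stats::var(df$index) == 0) stopf("fit_trend: zero variance in quarter index")
  if (method == "ols") {
    m <- lm(proportion ~ index, data = df)
    slope <- unname(coef(m)[2])
    rss <- sum(residuals(m)^2)
    if (rss < 1e-24) {
      # perfect fit: degenerate OLS (CI width 0; p = 1 iff the slope is 0)
      ci <- c(slope, slope)
      p <- if (abs(slope) < 1e-12) 1 else 0
    } else {
      ci <- unname(confint(m, "index", level = conf_level))
      p <- summary(m)$coefficients["index", "Pr(>|t|)"]
    }
  } else {
    m <- stats::glm(cbind(numerator, denominator - numerator) ~ index,
                    family = stats::binomial(), data = df)
    slope <- unname(coef(m)[2])
    se <- summary(m)$coefficients["index", "Std. Error"]
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(slope - z * se, slope + z * se)
    p <- summary(m)$coefficients["index", "Pr(>|z|)"]
  }
  ts$fit <- list(slope = slope, ci_lower = ci[1], ci_upper = ci[2],
                 p_value = p, method = method, conf_level = conf_level)
  ts
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series: %d quarters>\n", nrow(x$series)))
  if (!is.null(x$fit)) {
    cat(sprintf("  slope=%.4g (%d%% CI %.4g to %.4g), P=%.3g [%s]\n",
                x$fit$slope, round(100 * x$fit$conf_level), x$fit$ci_lower,
                x$fit$ci_upper, x$fit$p_value, x$fit$method))
  }
  invisible(x)
}

# ---- Fisher exact ----------------------------------------------------------

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The p-value is computed by full hypergeometric enumeration: with the
#' margins fixed, the probabilities of all attainable tables are summed
#' over tables no more probable than the observed one (standard two-sided
#' convention). Also returns the row-proportion difference
#' `a/(a+b) - c/(c+d)`.
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#'   (`rbind(c(a, b), c(c, d))`)
#' @return list with `p_value` and `proportion_difference`
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("fisher_exact: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stopf("fisher_exact: counts must be nonnegative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    stopf("fisher_exact: empty margin")
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       proportion_difference = a / r1 - c_ / r2)
}
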
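test_that("criterion parsing and evaluation follow the word/code/stay grammar", {
  crit <- parse_criterion('word:"heparin"')
  expect_true(evaluate_criterion(crit, "got Heparin today."))
  expect_false(evaluate_criterion(crit, "heparin-free regimen x"))  # whole token
  wc <- parse_criterion('word:"occlusion*"')
  expect_true(evaluate_criterion(wc, "two occlusions seen"))
  expect_true(evaluate_criterion(wc, "an occlusion"))
  expect_false(evaluate_criterion(wc, "preocclusion state"))

  combo <- parse_criterion('(word:"heparin" AND code:"38.*") OR stay>=14')
  expect_true(evaluate_criterion(combo, "heparin given", codes = "38.93"))
  expect_false(evaluate_criterion(combo, "heparin given", codes = "99.04"))
  expect_true(evaluate_criterion(combo, "nothing", stay_days = 20))
  neg <- parse_criterion('NOT word:"trauma"')
  expect_true(evaluate_criterion(neg, "no issues"))

  expect_error(parse_criterion('word:"a" AND'), "parse error")
  expect_error(parse_criterion('bogus'), "parse error")
  expect_error(parse_criterion('(word:"a"'), "missing")
})

test_that("an always-true criterion gives proportion 1 in every quarter", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  ts <- quarterly_proportions(cx$docs, 'word:"pt" OR NOT word:"pt"')
  expect_true(all(ts$series$proportion == 1))
  expect_equal(sum(ts$series$denominator), nrow(cx$docs))
})

test_that("quarterly counts match a brute-force scan for an injected trend term", {
  cx <- std_corpus(n_per_group = 100, seed = 11,
                   trend_terms = data.frame(
                     term = c("newdrug", "risingterm"),
                     slope = c(0.08, 0.03), base = c(0, 0.01)))
  ts <- quarterly_proportions(cx$docs, 'word:"newdrug"')
  qmap <- cx$cohort$truth$quarter[cx$docs$admission_id]
  hit <- grepl("\\bnewdrug\\b", cx$docs$text)
  oracle <- vapply(seq_len(max(qmap)), function(q) sum(hit[qmap == q]), numeric(1))
  expect_equal(ts$series$numerator, oracle)
  # rising prevalence must actually rise
  f <- fit_trend(ts)
  expect_gt(f$fit$slope, 0)
  expect_lt(f$fit$p_value, 0.01)
})

test_that("admissions outside the supplied quarters are an error", {
  cx <- std_corpus(n_per_group = 25, seed = 3)
  expect_error(quarterly_proportions(cx$docs, 'word:"pt"',
                                     quarters = as.Date("2006-01-01")),
               "outside all quarters")
})

test_that("trend fitting handles constant and perfectly linear series", {
  const <- fit_trend(trend_series(rep(10, 8), rep(100, 8)))
  expect_equal(const$fit$slope, 0)
  expect_equal(const$fit$p_value, 1)

  exact <- fit_trend(trend_series(round((0.01 + 0.002 * (1:10)) * 1000),
                                  rep(1000, 10)))
  expect_equal(exact$fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(exact$fit$ci_upper - exact$fit$ci_lower, 0)
  expect_lt(exact$fit$p_value, 1e-10)

  expect_error(fit_trend(trend_series(c(1, 2), c(10, 10))), "at least 3 quarters")

  glmfit <- fit_trend(trend_series(c(5, 10, 20, 35, 50), rep(100, 5)),
                      method = "binomial")
  expect_gt(glmfit$fit$slope, 0)
  expect_lt(glmfit$fit$p_value, 0.01)
})

test_that("slope recovery: the 95% CI covers a true slope in most seeded replicates", {
  n_q <- 28; n_per_q <- 500; true_slope <- 0.005
  p <- 0.01 + true_slope * (0:(n_q - 1))
  covered <- with_seed_test(100, {
    vapply(1:30, function(r) {
      y <- rbinom(n_q, n_per_q, p)
      f <- fit_trend(trend_series(y, rep(n_per_q, n_q)))
      f$fit$ci_lower <= true_slope && true_slope <= f$fit$ci_upper
    }, logical(1))
  })
  expect_gte(mean(covered), 0.85)
})

test_that("fisher_exact matches enumeration and stats::fisher.test", {
  sym <- fisher_exact(rbind(c(5, 5), c(5, 5)))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$proportion_difference, 0)

  hard <- fisher_exact(rbind(c(3, 0), c(0, 3)))
  expect_equal(hard$p_value, fisher_oracle(3, 0, 0, 3))
  expect_equal(hard$p_value, 0.1)

  tables <- list(c(1, 9, 11, 3), c(2, 7, 8, 2), c(10, 2, 3, 15),
                 c(1, 1, 1, 1), c(0, 5, 5, 0), c(12, 4, 5, 9))
  for (tb in tables) {
    ours <- fisher_exact(rbind(tb[1:2], tb[3:4]))
    expect_equal(ours$p_value,
                 stats::fisher.test(rbind(tb[1:2], tb[3:4]))$p.value,
                 tolerance = 1e-10)
    expect_equal(ours$p_value, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "empty margin")
  expect_error(fisher_exact(rbind(c(-1, 1), c(1, 1))), "nonnegative")
})
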
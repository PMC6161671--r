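# brute-force AUC oracle: all case-control pairs, ties worth 1/2
auc_pairs <- function(cases, controls, higher_is_positive = TRUE) {
  if (!higher_is_positive) { cases <- -cases; controls <- -controls }
  g <- expand.grid(ca = cases, co = controls)
  mean((g$ca > g$co) + 0.5 * (g$ca == g$co))
}

test_that("AUC equals the pair-comparison oracle including ties", {
  r <- ifn_roc(c(5, 3, 3, 1), c(1, 1, 0, 0), higher_is_positive = TRUE)
  expect_equal(r$auc, 3.5 / 4)  # one tied pair
  # perfect separation (pROC warns that the DeLong CI is degenerate)
  expect_equal(suppressWarnings(
    ifn_roc(c(3, 1, 2), c(1, 0, 0), higher_is_positive = TRUE))$auc, 1.0)
  set.seed(21)
  for (i in 1:10) {
    score <- round(rnorm(60), 1)  # rounding forces ties
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    for (hi in c(TRUE, FALSE)) {
      r <- ifn_roc(score, y, higher_is_positive = hi)
      expect_equal(r$auc, auc_pairs(score[y == 1], score[y == 0], hi))
    }
  }
})

test_that("AUC is invariant to reflecting scores with flipped polarity", {
  set.seed(22)
  score <- rnorm(80, 5, 1.4)
  y <- rbinom(80, 1, plogis(2 * (4.8 - score)))
  if (length(unique(y)) < 2) skip("degenerate draw")
  r1 <- ifn_roc(score, y, higher_is_positive = FALSE)
  r2 <- ifn_roc(-score, y, higher_is_positive = TRUE)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$auc_ci, r2$auc_ci)
})

test_that("shuffled labels give a null AUC near 0.5", {
  set.seed(23)
  score <- rnorm(500)
  y <- sample(rep(0:1, each = 250))
  r <- ifn_roc(score, y)
  expect_gt(r$auc, 0.45)
  expect_lt(r$auc, 0.55)
  expect_error(ifn_roc(rnorm(5), rep(1, 5)), "both outcome classes")
})

test_that("Youden cutoff equals exhaustive search, ties to sensitivity", {
  set.seed(24)
  score <- c(rnorm(30, 4, 1), rnorm(70, 6, 1))  # cases lower
  y <- rep(c(1, 0), c(30, 70))
  r <- ifn_roc(score, y)
  yc <- youden_cutoff(r)
  # exhaustive scan over every candidate cutoff (inclusive rule)
  cand <- sort(unique(score))
  j <- vapply(cand, function(t)
    mean(score[y == 1] <= t) + mean(score[y == 0] > t) - 1, numeric(1))
  expect_equal(yc$youden_j, max(j))
  best <- cand[j == max(j)]
  expect_true(yc$cutoff %in% best)
  # confusion counts at the chosen cutoff are consistent
  cnt <- attr(yc$metrics, "counts")
  expect_equal(unname(cnt["tp"] + cnt["fn"]), 30)
  expect_equal(yc$sensitivity, cnt[["tp"]] / 30)
  # perfectly separated scores reach J = 1
  sep <- suppressWarnings(ifn_roc(c(1, 2, 8, 9), c(1, 1, 0, 0)))
  expect_equal(youden_cutoff(sep)$youden_j, 1)
})

test_that("rule-in cutoff respects the specificity floor monotonically", {
  set.seed(25)
  score <- c(rnorm(40, 4, 1.2), rnorm(80, 6, 1.2))
  y <- rep(c(1, 0), c(40, 80))
  r <- ifn_roc(score, y)
  prev_sens <- 1
  for (ms in c(0.5, 0.7, 0.8, 0.9, 0.95)) {
    rc <- rule_in_cutoff(r, ms)
    expect_gte(rc$specificity, ms)
    expect_lte(rc$sensitivity, prev_sens + 1e-12)
    prev_sens <- rc$sensitivity
  }
  # fully tied scores leave no observed cutoff with high specificity
  tied <- ifn_roc(c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_error(rule_in_cutoff(tied, 0.8), "unattainable|achievable")
  expect_error(rule_in_cutoff(r, 1.2), "min_specificity")
})

test_that("diagnostics reproduce the published operating points", {
  yc <- do.call(diagnostics, as.list(youden_confusion()))
  est <- setNames(yc$estimate, yc$metric)
  expect_equal(unname(est["sensitivity"]), 18 / 19)
  expect_equal(unname(est["ppv"]), 18 / 52)           # 0.346 -> 35%
  expect_equal(unname(est["npv"]), 52 / 53)           # 0.981 -> 98%
  expect_equal(round(100 * unname(est[c("sensitivity", "specificity",
                                        "ppv", "npv")])),
               c(95, 60, 35, 98), ignore_attr = TRUE)
  expect_equal(unname(est["youden_j"]),
               unname(est["sensitivity"] + est["specificity"] - 1))
  us <- do.call(diagnostics, as.list(ultrasound_confusion()))
  ppv <- us[us$metric == "ppv", ]
  expect_equal(ppv$estimate, 1 / 3, tolerance = 1e-9)
  expect_equal(round(100 * c(ppv$lower, ppv$upper)), c(17, 55))
})

test_that("Wilson interval matches prop.test and respects bounds", {
  # independent oracle: score interval from prop.test without correction
  set.seed(26)
  for (i in 1:12) {
    n <- sample(5:60, 1)
    x <- sample(0:n, 1)
    w <- wilson_ci(x, n)
    pt <- prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(w[1, ]), as.numeric(pt), tolerance = 1e-9)
    expect_gte(x / n, w[1, "lower"])
    expect_lte(x / n, w[1, "upper"])
  }
  expect_equal(unname(wilson_ci(0, 10)[1, "lower"]), 0)
  expect_equal(unname(wilson_ci(10, 10)[1, "upper"]), 1)
})

test_that("degenerate predicted strata give NaN PPV with warning", {
  expect_warning(d <- diagnostics(0, 0, 5, 5), "undefined")
  expect_true(is.nan(d$estimate[d$metric == "ppv"]))
  expect_error(diagnostics(0, 5, 0, 5), "strata")
})

test_that("a curve compared with itself gives chi-squared 0, p 1", {
  set.seed(27)
  score <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  r <- ifn_roc(score, y)
  res <- compare_auc_paired(r, r)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  r2 <- ifn_roc(score[-1], y[-1])
  expect_error(compare_auc_paired(r, r2), "same samples")
})

test_that("DeLong comparison holds its type-I error on null data", {
  set.seed(28)
  reps <- 400
  n <- 100
  rej <- 0
  for (i in seq_len(reps)) {
    y <- rep(0:1, each = n / 2)
    r1 <- ifn_roc(rnorm(n), y)
    r2 <- ifn_roc(rnorm(n), y)
    if (compare_auc_paired(r1, r2)$p.value < 0.05) rej <- rej + 1
  }
  # binomial(400, 0.05): 3 sd band around 20
  expect_gt(rej, 5)
  expect_lt(rej, 35)
})
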
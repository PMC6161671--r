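#' Wilson score interval for a binomial proportion
#'
#' Two-sided score-test interval without continuity correction; always
#' contained in `[0, 1]` and always covering the point estimate `x/n`.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Matrix with columns `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (any(n <= 0, na.rm = TRUE)) stop("`n` must be positive")
  if (any(x < 0 | x > n, na.rm = TRUE)) stop("`x` must lie in [0, n]")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' ROC curve for an interferon score
#'
#' Sweeps every observed score value as a candidate cutoff, computing
#' sensitivity and specificity with the *inclusive* rule used for the
#' delta-Ct thresholds: a sample is called positive when its score is
#' `<=` the cutoff (default polarity: lower delta-Ct = more interferon =
#' positive) or `>=` the cutoff when `higher_is_positive`. The area under
#' the curve equals the Mann-Whitney probability with ties counted 1/2;
#' its confidence interval comes from the DeLong variance.
#'
#' @param score Numeric per-sample scores; `NA` excluded (with their
#'   outcomes).
#' @param outcome Binary outcome per sample: logical, 0/1, or a factor
#'   whose *second* level is the positive class.
#' @param higher_is_positive If `TRUE`, larger scores indicate the
#'   positive class (use for reflected scores).
#' @param conf Confidence level for the AUC interval.
#' @return Object of class `ifn_roc`: `thresholds` data frame (threshold,
#'   sensitivity, specificity), `auc`, `auc_ci`, counts, and the inputs.
#' @export
ifn_roc <- function(score, outcome, higher_is_positive = FALSE,
                    conf = 0.95) {
  y <- to_binary(outcome)
  ok <- !is.na(score) & !is.na(y)
  score <- score[ok]; y <- y[ok]
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  s <- if (higher_is_positive) -score else score  # lower s = positive
  cases <- s[y == 1L]; controls <- s[y == 0L]
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(cases <= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(controls > t), numeric(1L))
  tab <- data.frame(
    threshold = if (higher_is_positive) -c(Inf, thr) else c(-Inf, thr),
    sensitivity = c(0, sens), specificity = c(1, spec))
  # trapezoid over (1 - spec, sens); equals Mann-Whitney with ties = 1/2
  fpr <- 1 - tab$specificity
  auc <- sum(diff(fpr) * (tab$sensitivity[-1L] +
                            tab$sensitivity[-nrow(tab)]) / 2)
  proc <- pROC::roc(response = y, predictor = s, direction = ">",
                    levels = c(0L, 1L), quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(proc, conf.level = conf,
                                method = "delong"))[c(1L, 3L)]
  structure(list(thresholds = tab, auc = auc,
                 auc_ci = c(lower = ci[1L], upper = ci[2L]),
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                 higher_is_positive = higher_is_positive, conf = conf,
                 score = score, outcome = y, proc = proc),
            class = "ifn_roc")
}

#' @export
print.ifn_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%.0f%% CI %.3f to %.3f); %d positives, %d negatives\n",
              x$auc, 100 * x$conf, x$auc_ci[1L], x$auc_ci[2L],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test comparing two paired AUCs
#'
#' Compares the areas under two ROC curves built from the same samples
#' (e.g. Score-A versus Score-B for the same individuals), reporting the
#' statistic as chi-squared on 1 degree of freedom (the square of the
#' DeLong z).
#'
#' @param curve1,curve2 [ifn_roc()] objects over identical samples and
#'   outcomes.
#' @return An `htest`.
#' @export
compare_auc_paired <- function(curve1, curve2) {
  if (!inherits(curve1, "ifn_roc") || !inherits(curve2, "ifn_roc"))
    stop("both arguments must be `ifn_roc` objects")
  if (length(curve1$outcome) != length(curve2$outcome) ||
      any(curve1$outcome != curve2$outcome))
    stop("curves must be built on the same samples and outcomes")
  if (isTRUE(all.equal(curve1$score, curve2$score)) &&
      curve1$higher_is_positive == curve2$higher_is_positive) {
    # identical predictors: difference is exactly zero, variance degenerate
    return(structure(list(statistic = c("chi-squared" = 0),
                          parameter = c(df = 1L), p.value = 1,
                          method = "DeLong test for two paired ROC curves",
                          data.name = "curve1 vs curve2"),
                     class = "htest"))
  }
  rt <- pROC::roc.test(curve1$proc, curve2$proc, method = "delong",
                       paired = TRUE)
  z <- as.numeric(rt$statistic)
  structure(list(statistic = c("chi-squared" = z^2),
                 parameter = c(df = 1L), p.value = rt$p.value,
                 estimate = c(auc1 = curve1$auc, auc2 = curve2$auc),
                 method = "DeLong test for two paired ROC curves",
                 data.name = "curve1 vs curve2"),
            class = "htest")
}

#' Diagnostic accuracy metrics with Wilson intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' Youden's J from a 2 x 2 confusion table, each proportion with a
#' two-sided Wilson score interval.
#'
#' @param tp,fp,fn,tn Confusion-matrix counts. Alternatively pass a 2 x 2
#'   matrix `rbind(c(tp, fp), c(fn, tn))` as `tp`.
#' @param conf Confidence level.
#' @return Object of class `diag_metrics`: data frame with columns
#'   `metric`, `numerator`, `denominator`, `estimate`, `lower`, `upper`;
#'   counts kept as an attribute. PPV/NPV are `NaN` (with a warning) when
#'   their denominator is zero.
#' @export
diagnostics <- function(tp, fp = NULL, fn = NULL, tn = NULL, conf = 0.95) {
  if (is.matrix(tp)) {
    m <- tp
    if (!all(dim(m) == 2L)) stop("confusion matrix must be 2 x 2")
    tp <- m[1L, 1L]; fp <- m[1L, 2L]; fn <- m[2L, 1L]; tn <- m[2L, 2L]
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("both outcome strata must be non-empty (tp+fn > 0, tn+fp > 0)")
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp,
           ppv = tp + fp, npv = tn + fn)
  est <- num / den
  if (any(den == 0)) warning("PPV/NPV undefined: empty predicted stratum")
  ci <- matrix(NA_real_, 4L, 2L, dimnames = list(NULL, c("lower", "upper")))
  ok <- den > 0
  ci[ok, ] <- wilson_ci(num[ok], den[ok], conf)
  out <- data.frame(metric = names(num), numerator = unname(num),
                    denominator = unname(den), estimate = unname(est),
                    lower = ci[, 1L], upper = ci[, 2L],
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(
    metric = "youden_j", numerator = NA_real_, denominator = NA_real_,
    estimate = est[["sensitivity"]] + est[["specificity"]] - 1,
    lower = NA_real_, upper = NA_real_))
  attr(out, "counts") <- counts
  attr(out, "conf") <- conf
  class(out) <- c("diag_metrics", "data.frame")
  out
}

#' @export
print.diag_metrics <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Confusion: TP=%d FP=%d FN=%d TN=%d\n",
              cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"]))
  for (i in seq_len(nrow(x))) {
    if (x$metric[i] == "youden_j") {
      cat(sprintf("  Youden J     %.2f\n", x$estimate[i]))
    } else {
      cat(sprintf("  %-12s %3.0f%% (%.0f%% to %.0f%%)\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$lower[i], 100 * x$upper[i]))
    }
  }
  invisible(x)
}

# confusion counts at an inclusive cutoff on the internal scale
confusion_at <- function(curve, thr_internal) {
  cases <- curve$score[curve$outcome == 1L]
  controls <- curve$score[curve$outcome == 0L]
  if (curve$higher_is_positive) { cases <- -cases; controls <- -controls }
  c(tp = sum(cases <= thr_internal), fp = sum(controls <= thr_internal),
    fn = sum(cases > thr_internal), tn = sum(controls > thr_internal))
}

cutoff_result <- function(curve, i, rule) {
  tab <- curve$thresholds
  thr <- tab$threshold[i]
  thr_internal <- if (curve$higher_is_positive) -thr else thr
  cnt <- confusion_at(curve, thr_internal)
  structure(list(cutoff = thr, rule = rule,
                 sensitivity = tab$sensitivity[i],
                 specificity = tab$specificity[i],
                 youden_j = tab$sensitivity[i] + tab$specificity[i] - 1,
                 metrics = diagnostics(cnt[["tp"]], cnt[["fp"]],
                                       cnt[["fn"]], cnt[["tn"]],
                                       conf = curve$conf),
                 higher_is_positive = curve$higher_is_positive),
            class = "ifn_cutoff")
}

#' @export
print.ifn_cutoff <- function(x, ...) {
  op <- if (x$higher_is_positive) ">=" else "<="
  cat(sprintf("%s cutoff: positive when score %s %.4g (Youden J = %.2f)\n",
              x$rule, op, x$cutoff, x$youden_j))
  print(x$metrics)
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The observed threshold maximising Youden's J = sensitivity +
#' specificity - 1; exact ties are broken toward higher sensitivity.
#'
#' @param curve An [ifn_roc()].
#' @return Object of class `ifn_cutoff`: the cutoff (in score units, with
#'   the inclusive comparison direction of the curve) plus its
#'   [diagnostics()].
#' @export
youden_cutoff <- function(curve) {
  if (!inherits(curve, "ifn_roc")) stop("`curve` must be an `ifn_roc`")
  tab <- curve$thresholds
  j <- tab$sensitivity + tab$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  i <- best[which.max(tab$sensitivity[best])]
  cutoff_result(curve, i, "Youden")
}

#' Rule-in cutoff at a specificity floor
#'
#' The most sensitive observed threshold whose specificity is at least
#' `min_specificity` - the operating point for enriching a prevention
#' study with high-risk individuals. Ties in sensitivity are resolved
#' toward higher specificity.
#'
#' @param curve An [ifn_roc()].
#' @param min_specificity Required specificity, in (0, 1).
#' @return Object of class `ifn_cutoff`.
#' @export
rule_in_cutoff <- function(curve, min_specificity = 0.8) {
  if (!inherits(curve, "ifn_roc")) stop("`curve` must be an `ifn_roc`")
  if (min_specificity <= 0 || min_specificity >= 1)
    stop("`min_specificity` must lie in (0, 1)")
  tab <- curve$thresholds
  # only observed cutoffs qualify: the -Inf boundary (call nobody
  # positive) is not an operating point
  ok <- which(tab$specificity >= min_specificity &
                is.finite(tab$threshold))
  if (!length(ok))
    stop(sprintf("specificity %.2f unattainable; maximum achievable is %.3f",
                 min_specificity, max(tab$specificity)))
  best <- ok[tab$sensitivity[ok] >= max(tab$sensitivity[ok]) - 1e-12]
  i <- best[which.max(tab$specificity[best])]
  cutoff_result(curve, i, sprintf("Rule-in (spec >= %.2f)", min_specificity))
}

# coerce outcomes to 0/1 integers (second factor level / TRUE / 1 = positive)
to_binary <- function(outcome) {
  if (is.factor(outcome)) {
    if (nlevels(outcome) != 2L) stop("outcome factor must have 2 levels")
    return(as.integer(outcome) - 1L)
  }
  if (is.logical(outcome)) return(as.integer(outcome))
  v <- as.numeric(outcome)
  if (!all(v %in% c(0, 1) | is.na(v)))
    stop("outcome must be binary (0/1, logical, or 2-level factor)")
  as.integer(v)
}
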
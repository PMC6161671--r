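#' Fit the multiply-imputed penalised prognostic model
#'
#' The full modelling sequence for predicting 12-month progression from
#' baseline covariates and interferon scores: (1) multiple imputation by
#' chained equations of incomplete predictors; (2) univariable screening
#' of each candidate at the `alpha` significance level, pooled by Rubin's
#' rules; (3) a pooled unpenalised multivariable logistic model over the
#' retained predictors; and (4), per completed dataset, an L1-penalised
#' logistic model with its penalty chosen by leave-one-out
#' cross-validation and the one-standard-error rule, whose coefficients
#' are averaged across imputations (the across-imputation range is also
#' kept).
#'
#' @param data Data frame holding the outcome column plus candidate
#'   predictors (numeric or two-level factors); interferon scores should
#'   be supplied on the reflected (-dCt) scale so that positive
#'   coefficients mean more interferon, more risk.
#' @param outcome Name of the binary outcome column; must be complete.
#' @param predictors Candidate predictor columns (default: all others).
#' @param m Number of imputations (default 20).
#' @param cycles Chained-equation sweeps (default 10).
#' @param alpha Univariable retention level (default 0.10).
#' @param seed Master seed governing the imputation streams.
#' @param nlambda,lambda_min_ratio Penalty-path controls passed to
#'   [cv_lasso_logistic()].
#' @param penalized Fit the per-imputation penalised models (default
#'   `TRUE`). Setting `FALSE` skips stage (4) — useful when only the
#'   pooled multivariable model is of interest, e.g. on large simulated
#'   cohorts where n leave-one-out folds are wasteful.
#' @param conf Confidence level for all reported intervals.
#' @return Object of class `ifn_prognosis` with components `screen`
#'   ([univariable_screen()] result), `multivariable` (pooled
#'   [pool_rubin()] table with odds ratios), `penalized` (per-predictor
#'   mean/min/max penalised coefficient and the odds ratio of the mean),
#'   `lambda_1se` (per imputation), `imputations`, `n`, `m`, `call`.
#' @seealso [simulate_cohort()] for generating cohorts with a known
#'   progression model.
#' @export
fit_prognostic <- function(data, outcome = "progression",
                           predictors = NULL, m = 20L, cycles = 10L,
                           alpha = 0.10, seed = 1L, nlambda = 100L,
                           lambda_min_ratio = 1e-3, penalized = TRUE,
                           conf = 0.95) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome,
                                      "' not found")
  if (anyNA(data[[outcome]])) stop("outcome must be non-missing")
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  dat <- data[, c(outcome, predictors), drop = FALSE]
  n <- nrow(dat)

  imps <- impute_chained(dat, m = m, cycles = cycles, seed = seed)
  screen <- univariable_screen(imps, outcome, predictors, alpha = alpha,
                               conf = conf)
  kept <- screen$kept
  if (!length(kept)) stop("no predictor passed univariable screening")

  y <- to_binary(dat[[outcome]])
  mv_est <- mv_var <- NULL
  pen_coef <- matrix(NA_real_, m, length(kept),
                     dimnames = list(NULL, kept))
  lambda_1se <- numeric(m)
  for (k in seq_len(m)) {
    dk <- completed(imps, k)
    X <- do.call(cbind, lapply(dk[kept], as.numeric))
    colnames(X) <- kept
    fit <- suppressWarnings(
      glm(y ~ X, family = binomial()))
    est <- coef(fit)[-1L]
    names(est) <- kept
    vr <- diag(vcov(fit))[-1L]
    names(vr) <- kept
    mv_est <- rbind(mv_est, est)
    mv_var <- rbind(mv_var, vr)
    if (penalized) {
      cv <- cv_lasso_logistic(X, y, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)
      lambda_1se[k] <- cv$lambda_1se
      pen_coef[k, ] <- coef(cv$fit, s = cv$lambda_1se)[-1L]
    }
  }
  multivariable <- pool_rubin(mv_est, mv_var,
                              df_com = n - length(kept) - 1L, conf = conf)
  multivariable$or <- exp(multivariable$estimate)
  multivariable$or_low <- exp(multivariable$conf.low)
  multivariable$or_high <- exp(multivariable$conf.high)

  pen_tab <- if (penalized) data.frame(
    term = kept,
    coef_mean = colMeans(pen_coef),
    coef_min = apply(pen_coef, 2L, min),
    coef_max = apply(pen_coef, 2L, max),
    or = exp(colMeans(pen_coef)),
    row.names = NULL, stringsAsFactors = FALSE) else NULL

  structure(list(screen = screen, multivariable = multivariable,
                 penalized = pen_tab, lambda_1se = lambda_1se,
                 imputations = imps, outcome = outcome,
                 predictors = predictors, kept = kept, n = n, m = m,
                 alpha = alpha, conf = conf, seed = seed,
                 call = match.call()),
            class = "ifn_prognosis")
}

#' @export
print.ifn_prognosis <- function(x, ...) {
  cat("Prognostic model of progression (multiple imputation + penalised logistic regression)\n")
  cat(sprintf("  n = %d, events = %d, m = %d imputations, screening alpha = %.2f\n",
              x$n, sum(to_binary(x$imputations$data[[x$outcome]])), x$m,
              x$alpha))
  if (length(x$screen$excluded))
    cat("  Excluded at screening:", paste(x$screen$excluded,
                                          collapse = ", "), "\n")
  t <- x$multivariable
  p <- x$penalized
  cat("  Multivariable (pooled) and penalised estimates:\n")
  for (i in seq_len(nrow(t)))
    cat(sprintf("    %-26s OR %6.2f (%5.2f to %6.2f), p = %-8.3g%s\n",
                t$term[i], t$or[i], t$or_low[i], t$or_high[i],
                t$p.value[i],
                if (is.null(p)) "" else
                  sprintf("  penalised %.3f -> OR %.3f",
                          p$coef_mean[i], p$or[i])))
  invisible(x)
}

#' @export
summary.ifn_prognosis <- function(object, ...) {
  structure(list(screen = object$screen$table,
                 excluded = object$screen$excluded,
                 multivariable = object$multivariable,
                 penalized = object$penalized,
                 lambda_1se = object$lambda_1se,
                 n = object$n, m = object$m), class = "summary.ifn_prognosis")
}

#' @export
print.summary.ifn_prognosis <- function(x, ...) {
  cat("Univariable screening (pooled):\n")
  print(x$screen[, c("term", "or", "or_low", "or_high", "p.value")],
        digits = 3L, row.names = FALSE)
  if (length(x$excluded))
    cat("Excluded:", paste(x$excluded, collapse = ", "), "\n")
  cat("\nMultivariable pooled model:\n")
  print(x$multivariable[, c("term", "or", "or_low", "or_high",
                            "p.value")], digits = 3L, row.names = FALSE)
  cat("\nPenalised coefficients (mean across imputations, with range):\n")
  print(x$penalized, digits = 3L, row.names = FALSE)
  cat(sprintf("\nlambda_1se across imputations: %.4g to %.4g\n",
              min(x$lambda_1se), max(x$lambda_1se)))
  invisible(x)
}

#' Coefficients of the prognostic model
#'
#' @param object An [fit_prognostic()] result.
#' @param type `"penalized"` (default): mean penalised coefficients;
#'   `"multivariable"`: pooled unpenalised log-odds.
#' @param ... Unused.
#' @export
coef.ifn_prognosis <- function(object, type = c("penalized",
                                                "multivariable"), ...) {
  type <- match.arg(type)
  if (type == "penalized")
    setNames(object$penalized$coef_mean, object$penalized$term)
  else
    setNames(object$multivariable$estimate, object$multivariable$term)
}
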
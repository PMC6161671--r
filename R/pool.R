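#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and their variances: the
#' pooled estimate is the mean, the total variance is
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance, and inference uses the
#' Barnard-Rubin adjusted degrees of freedom (the classical large-sample
#' formula when `df_com = Inf`).
#'
#' @param estimates m x p matrix (rows = imputations) of estimates, with
#'   column names; a list of equally named vectors is also accepted.
#' @param variances m x p matrix of squared standard errors, aligned with
#'   `estimates`.
#' @param df_com Complete-data residual degrees of freedom (e.g.
#'   `n - p - 1` for a logistic model); `Inf` for the unadjusted formula.
#' @param conf Confidence level.
#' @return Object of class `mi_pooled`: data frame with columns `term`,
#'   `estimate`, `W`, `B`, `T`, `std.error`, `df`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf, conf = 0.95) {
  if (is.list(estimates) && !is.matrix(estimates))
    estimates <- do.call(rbind, estimates)
  if (is.list(variances) && !is.matrix(variances))
    variances <- do.call(rbind, variances)
  estimates <- as.matrix(estimates); variances <- as.matrix(variances)
  m <- nrow(estimates)
  if (m < 2L) stop("pooling requires m >= 2 imputations")
  if (!identical(dim(estimates), dim(variances)))
    stop("`estimates` and `variances` must be aligned")
  if (!is.null(colnames(variances)) &&
      !identical(colnames(estimates), colnames(variances)))
    stop("coefficient names differ between estimates and variances")

  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2L, var)
  Tv <- W + (1 + 1 / m) * B

  r <- (1 + 1 / m) * B / W                     # relative variance increase
  nu_old <- (m - 1) * (1 + 1 / r)^2            # Inf when B = 0
  if (is.finite(df_com)) {
    gamma <- (1 + 1 / m) * B / Tv
    nu_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - gamma)
    df <- 1 / (1 / nu_old + 1 / nu_obs)
    df[B == 0] <- nu_obs[B == 0]
  } else {
    df <- nu_old
    df[B == 0] <- Inf
  }
  se <- sqrt(Tv)
  stat <- qbar / se
  p <- 2 * pt(-abs(stat), df)
  crit <- qt(1 - (1 - conf) / 2, df)
  out <- data.frame(term = colnames(estimates) %||%
                      paste0("b", seq_along(qbar)),
                    estimate = unname(qbar), W = unname(W), B = unname(B),
                    T = unname(Tv), std.error = unname(se),
                    df = unname(df), statistic = unname(stat),
                    p.value = unname(p),
                    conf.low = unname(qbar - crit * se),
                    conf.high = unname(qbar + crit * se),
                    stringsAsFactors = FALSE)
  class(out) <- c("mi_pooled", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Firth bias-reduced logistic regression (score correction with hat
# values); used as a fallback when ordinary ML separates.
firth_logistic <- function(x, y, maxit = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  beta <- rep(0, ncol(x))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(x %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    XW <- x * sqrt(w)
    info <- crossprod(XW) + diag(1e-10, ncol(x))
    hat <- rowSums((XW %*% chol2inv(chol(info))) * XW)
    U <- crossprod(x, y - p + hat * (0.5 - p))
    delta <- solve(info, U)
    beta <- beta + as.numeric(delta)
    if (max(abs(delta)) < tol) break
  }
  list(coefficients = beta, vcov = chol2inv(chol(info)))
}

# single-covariate logistic fit returning slope estimate and variance;
# falls back to Firth when the ML fit separates
uni_logit <- function(y, x) {
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  est <- coef(fit)[["x"]]
  se2 <- vcov(fit)["x", "x"]
  if (!is.finite(est) || !is.finite(se2) || sqrt(se2) > 50 ||
      abs(est) > 20) {
    warning("possible separation in univariable fit; ",
            "using Firth bias-reduced logistic regression")
    ff <- firth_logistic(cbind(1, x), y)
    est <- ff$coefficients[2L]
    se2 <- ff$vcov[2L, 2L]
  }
  c(est = est, var = se2)
}

#' Univariable screening of candidate predictors
#'
#' Fits a single-covariate logistic regression of the outcome on each
#' candidate predictor within every completed dataset, pools the slope by
#' Rubin's rules, and excludes predictors whose pooled p-value exceeds
#' `alpha` from the multivariable set.
#'
#' @param imputations An [impute_chained()] result whose data contain the
#'   outcome column.
#' @param outcome Name of the binary outcome column (must be complete).
#' @param predictors Candidate predictor names (default: all other
#'   columns).
#' @param alpha Significance level for retention (default 0.10).
#' @param conf Confidence level for the reported intervals.
#' @return Object of class `screen_result`: `table` (per-predictor pooled
#'   log-OR, OR, CI, p), `kept`, `excluded`, `alpha`.
#' @export
univariable_screen <- function(imputations, outcome,
                               predictors = NULL, alpha = 0.10,
                               conf = 0.95) {
  if (!inherits(imputations, "imputation_set"))
    stop("`imputations` must be an `imputation_set`")
  dat1 <- completed(imputations, 1L)
  if (!outcome %in% names(dat1)) stop("outcome column '", outcome,
                                      "' not found")
  if (is.null(predictors)) predictors <- setdiff(names(dat1), outcome)
  n <- nrow(dat1)
  rows <- lapply(predictors, function(pv) {
    per <- vapply(imputations$imputations, function(d)
      uni_logit(to_binary(d[[outcome]]), as.numeric(d[[pv]])),
      numeric(2L))
    pooled <- pool_rubin(matrix(per["est", ], ncol = 1L,
                                dimnames = list(NULL, pv)),
                         matrix(per["var", ], ncol = 1L),
                         df_com = n - 2L, conf = conf)
    pooled
  })
  tab <- do.call(rbind, rows)
  tab$or <- exp(tab$estimate)
  tab$or_low <- exp(tab$conf.low)
  tab$or_high <- exp(tab$conf.high)
  kept <- tab$term[tab$p.value <= alpha]
  structure(list(table = tab, kept = kept,
                 excluded = setdiff(predictors, kept), alpha = alpha),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, digits = 3L, ...) {
  cat(sprintf("Univariable screening (retain at p <= %.2f):\n", x$alpha))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-26s OR %6.2f (%.2f to %.2f), p = %-7.3g %s\n",
                t$term[i], t$or[i], t$or_low[i], t$or_high[i],
                t$p.value[i],
                if (t$term[i] %in% x$kept) "" else "[excluded]"))
  invisible(x)
}
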
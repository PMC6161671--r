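#' L1-penalised logistic regression
#'
#' Fits the lasso-penalised logistic model
#' `(1/n) * negative log-likelihood + lambda * sum(|beta_j|)` over a
#' descending path of penalties by cyclic coordinate descent on the
#' iteratively reweighted least squares approximation. Predictors are
#' standardised internally (mean 0, population SD 1) so the penalty
#' treats them symmetrically; coefficients are reported back on the
#' original scale. The intercept is never penalised.
#'
#' At `lambda >= lambda_max = max_j |X_j'(y - mean(y))| / n` (standardised
#' X) every slope is exactly zero; at `lambda = 0` the fit coincides with
#' the unpenalised maximum-likelihood solution.
#'
#' @param x Numeric matrix of predictors (n x p), with column names.
#' @param y Binary outcome (0/1, logical, or 2-level factor); at least
#'   two events and two non-events.
#' @param lambda Optional user path (sorted descending internally). By
#'   default `nlambda` log-spaced values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Default path controls.
#' @param standardize Standardise predictors internally (default `TRUE`).
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default `1e-7`).
#' @param maxit Maximum IRLS iterations per penalty.
#' @return Object of class `lasso_logistic`: `lambda`, `a0` (intercepts),
#'   `beta` (p x nlambda coefficient matrix, original scale), `df`
#'   (active-set sizes), `lambda_max`, standardisation constants.
#' @export
lasso_logistic <- function(x, y, lambda = NULL, nlambda = 100L,
                           lambda_min_ratio = 1e-3, standardize = TRUE,
                           tol = 1e-7, maxit = 100L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- to_binary(y)
  if (anyNA(x) || anyNA(y)) stop("`x` and `y` must be complete")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need at least 2 events and 2 non-events")
  n <- nrow(x); p <- ncol(x)

  if (standardize) {
    xm <- colMeans(x)
    xs <- sqrt(colMeans(sweep(x, 2L, xm)^2))
    if (any(xs <= 0)) stop("constant predictor(s): ",
                           paste(colnames(x)[xs <= 0], collapse = ", "))
  } else {
    xm <- rep(0, p); xs <- rep(1, p)
  }
  xstd <- sweep(sweep(x, 2L, xm), 2L, xs, "/")

  lambda_max <- max(abs(crossprod(xstd, y - mean(y)))) / n
  if (is.null(lambda)) {
    # start a hair above lambda_max so the null model is exact at the
    # top of the path despite floating-point equality at the KKT boundary
    lambda <- exp(seq(log(lambda_max * (1 + 1e-6)),
                      log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }

  fit <- lasso_path_cd(xstd, as.numeric(y), lambda, tol, as.integer(maxit))
  beta_std <- fit$beta
  beta <- beta_std / xs
  a0 <- fit$b0 - as.numeric(crossprod(beta, xm))
  dimnames(beta) <- list(colnames(x), NULL)
  structure(list(lambda = lambda, a0 = a0, beta = beta,
                 beta_std = beta_std, df = colSums(beta != 0),
                 lambda_max = lambda_max, xm = xm, xs = xs,
                 iterations = fit$iterations, n = n, tol = tol),
            class = "lasso_logistic")
}

#' @export
print.lasso_logistic <- function(x, ...) {
  cat(sprintf("L1-penalised logistic path: %d predictors, %d penalties (lambda %.4g .. %.4g)\n",
              nrow(x$beta), length(x$lambda), max(x$lambda), min(x$lambda)))
  invisible(x)
}

#' Coefficients of a penalised logistic fit at a given penalty
#'
#' @param object A [lasso_logistic()] fit.
#' @param s Penalty value; the closest value on the fitted path is used.
#' @param ... Unused.
#' @return Named vector `(Intercept)` plus slopes on the original scale.
#' @export
coef.lasso_logistic <- function(object, s = min(object$lambda), ...) {
  i <- which.min(abs(object$lambda - s))
  c("(Intercept)" = object$a0[i],
    setNames(object$beta[, i], rownames(object$beta)))
}

#' Predict from a penalised logistic fit
#'
#' @param object A [lasso_logistic()] fit.
#' @param newx Matrix of predictors on the original scale.
#' @param s Penalty value (closest path value used).
#' @param type `"response"` (probabilities) or `"link"` (log-odds).
#' @param ... Unused.
#' @export
predict.lasso_logistic <- function(object, newx, s = min(object$lambda),
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  b <- coef(object, s = s)
  eta <- as.numeric(b[1L] + as.matrix(newx) %*% b[-1L])
  if (type == "link") eta else plogis(eta)
}

# held-out binomial deviance, probabilities clipped away from 0/1
binomial_deviance <- function(y, p, eps = 1e-8) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

#' Leave-one-out cross-validation for the lasso penalty
#'
#' Computes the mean held-out binomial deviance over the n leave-one-out
#' folds for every penalty on the path, with its standard error, and
#' selects both the deviance-minimising penalty (`lambda_min`) and the
#' largest penalty whose mean deviance is within one standard error of
#' that minimum (`lambda_1se`, the parsimony rule used for the prognostic
#' model).
#'
#' @inheritParams lasso_logistic
#' @return Object of class `cv_lasso`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se` and the full-data `fit`.
#' @export
cv_lasso_logistic <- function(x, y, lambda = NULL, nlambda = 100L,
                              lambda_min_ratio = 1e-3, tol = 1e-7,
                              maxit = 100L) {
  x <- as.matrix(x)
  y <- to_binary(y)
  n <- nrow(x)
  if (n < 10L) stop("leave-one-out cross-validation needs n >= 10")
  fit <- lasso_logistic(x, y, lambda = lambda, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio, tol = tol,
                        maxit = maxit)
  lambda <- fit$lambda
  dev <- matrix(NA_real_, n, length(lambda))
  for (i in seq_len(n)) {
    fi <- lasso_logistic(x[-i, , drop = FALSE], y[-i], lambda = lambda,
                         tol = tol, maxit = maxit)
    eta <- fi$a0 + as.numeric(x[i, , drop = FALSE] %*% fi$beta)
    dev[i, ] <- binomial_deviance(y[i], plogis(eta))
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2L, sd) / sqrt(n)
  imin <- which.min(cvm)
  ok <- cvm <= cvm[imin] + cvsd[imin]
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[imin],
                 lambda_1se = max(lambda[ok]), fit = fit, n = n),
            class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(sprintf("LOOCV lasso: lambda_min = %.4g, lambda_1se = %.4g (n = %d)\n",
              x$lambda_min, x$lambda_1se, x$n))
  invisible(x)
}
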
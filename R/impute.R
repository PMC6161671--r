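#' Multiple imputation by chained equations
#'
#' Creates `m` completed copies of a data frame by iterating univariate
#' imputation models over the incomplete variables: predictive mean
#' matching (PMM, 5 donors, Bayesian parameter draw) for continuous
#' variables and a Bayesian logistic draw for binary variables, each
#' conditioned on all other variables. Observed cells are never altered.
#' The whole procedure is deterministic for a fixed `seed`: one master
#' seed spawns `m` independent sub-streams.
#'
#' @param data Data frame of numeric and binary (0/1 or two-level factor)
#'   columns. Every incomplete variable must be at least 50% observed.
#' @param m Number of completed datasets (default 20).
#' @param cycles Chained-equation sweeps per dataset (default 10).
#' @param seed Master seed (integer).
#' @return Object of class `imputation_set`: `imputations` (list of `m`
#'   completed data frames), `where` (logical matrix of imputed cells),
#'   `methods`, `m`, `cycles`, `seed`.
#' @export
impute_chained <- function(data, m = 20L, cycles = 10L, seed = 1L) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  if (m < 1L) stop("`m` must be >= 1")
  data <- as.data.frame(data)
  # factors to numeric 0/1 for modelling; remembered for output
  fac_cols <- vapply(data, is.factor, logical(1L))
  fac_levels <- lapply(data[fac_cols], levels)
  if (any(vapply(fac_levels, length, integer(1L)) != 2L))
    stop("factor columns must have exactly 2 levels")
  work <- data
  for (cn in names(which(fac_cols)))
    work[[cn]] <- as.integer(work[[cn]]) - 1L
  if (!all(vapply(work, is.numeric, logical(1L))))
    stop("all columns must be numeric or two-level factors")

  where <- is.na(as.matrix(work))
  miss_cols <- names(which(colSums(where) > 0L))
  for (cn in miss_cols) {
    frac_obs <- mean(!is.na(work[[cn]]))
    if (frac_obs == 0) stop("variable '", cn, "' has no observed values")
    if (frac_obs < 0.5)
      stop("variable '", cn, "' is less than 50% observed (",
           round(100 * frac_obs), "%)")
  }
  is_binary <- vapply(work, function(v) {
    u <- unique(v[!is.na(v)]); length(u) <= 2L && all(u %in% c(0, 1))
  }, logical(1L))
  methods <- setNames(ifelse(is_binary[miss_cols], "logreg", "pmm"),
                      miss_cols)
  # impute in order of increasing missingness
  miss_cols <- miss_cols[order(colSums(where)[miss_cols])]

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, m)
  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(sub_seeds[k])
    cur <- work
    for (cn in miss_cols) {  # initial fill: sample observed values
      nas <- is.na(cur[[cn]])
      obs <- cur[[cn]][!nas]
      cur[[cn]][nas] <- sample(obs, sum(nas), replace = TRUE)
    }
    for (cy in seq_len(if (length(miss_cols)) cycles else 0L)) {
      for (cn in miss_cols) {
        ry <- !where[, cn]
        xmat <- cbind(1, as.matrix(cur[setdiff(names(cur), cn)]))
        cur[[cn]][!ry] <- impute_one(cur[[cn]], ry, xmat, methods[[cn]])
      }
    }
    out <- cur
    for (cn in names(which(fac_cols)))
      out[[cn]] <- factor(fac_levels[[cn]][out[[cn]] + 1L],
                          levels = fac_levels[[cn]])
    imputations[[k]] <- out
  }
  structure(list(data = data, imputations = imputations, where = where,
                 methods = methods, m = m, cycles = cycles, seed = seed),
            class = "imputation_set")
}

# draw imputations for the missing entries of one variable
impute_one <- function(y, ry, xmat, method) {
  xobs <- xmat[ry, , drop = FALSE]
  xmis <- xmat[!ry, , drop = FALSE]
  yobs <- y[ry]
  qrx <- qr(xobs)
  keep <- qrx$pivot[seq_len(qrx$rank)]  # drop collinear columns
  xobs <- xobs[, keep, drop = FALSE]
  xmis <- xmis[, keep, drop = FALSE]

  if (method == "pmm") {
    fit <- lm.fit(xobs, yobs)
    beta <- fit$coefficients
    df <- max(length(yobs) - ncol(xobs), 1L)
    sigma2_hat <- sum(fit$residuals^2) / df
    sigma2_star <- sum(fit$residuals^2) / rchisq(1L, df)
    XtXinv <- chol2inv(qr.R(qr(xobs)))
    cv <- chol(XtXinv * sigma2_star + diag(1e-10, ncol(xobs)))
    beta_star <- beta + as.numeric(t(cv) %*% rnorm(ncol(xobs)))
    pred_obs <- as.numeric(xobs %*% beta)
    pred_mis <- as.numeric(xmis %*% beta_star)
    vapply(pred_mis, function(pm) {
      d <- abs(pred_obs - pm)
      donors <- order(d)[seq_len(min(5L, length(d)))]
      yobs[sample(donors, 1L)]
    }, numeric(1L))
  } else {  # Bayesian logistic draw
    fit <- suppressWarnings(glm.fit(xobs, yobs, family = binomial()))
    beta <- fit$coefficients
    w <- fit$weights
    info <- crossprod(xobs * sqrt(w)) + diag(1e-8, ncol(xobs))
    cv <- chol(chol2inv(chol(info)))
    beta_star <- beta + as.numeric(t(cv) %*% rnorm(ncol(xobs)))
    p <- plogis(as.numeric(xmis %*% beta_star))
    rbinom(length(p), 1L, p)
  }
}

#' Extract one completed dataset
#'
#' @param x An [impute_chained()] result.
#' @param i Index of the completed dataset, `1 <= i <= m`.
#' @return The i-th completed data frame.
#' @export
completed <- function(x, i = 1L) {
  if (!inherits(x, "imputation_set")) stop("`x` must be an `imputation_set`")
  if (i < 1L || i > x$m) stop("`i` must be in 1..m")
  x$imputations[[i]]
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Chained-equations imputation:", x$m, "completed datasets,",
      x$cycles, "cycles, seed", x$seed, "\n")
  if (length(x$methods)) {
    cat("Imputed variables:\n")
    for (cn in names(x$methods))
      cat(sprintf("  %-24s %-7s (%d missing)\n", cn, x$methods[[cn]],
                  sum(x$where[, cn])))
  } else cat("No missing cells.\n")
  invisible(x)
}
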
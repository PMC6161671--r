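#' Construct a Ct expression matrix
#'
#' Container for raw qPCR cycle-threshold (Ct) values, genes in rows and
#' samples in columns, together with the housekeeping reference gene used
#' for delta-Ct normalisation (typically peptidylprolyl isomerase A, PPIA).
#'
#' @param ct Numeric matrix of Ct values (PCR cycles). Rows must be named
#'   with unique gene symbols, columns with unique sample IDs. `NA` marks a
#'   missing measurement.
#' @param reference_gene Symbol of the reference (housekeeping) gene; must
#'   be one of `rownames(ct)`.
#' @return An object of class `ct_matrix`.
#' @seealso [delta_ct()], [read_ct_matrix()]
#' @export
ct_matrix <- function(ct, reference_gene) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)) || anyDuplicated(rownames(ct)))
    stop("`ct` must have unique rownames (gene symbols)")
  if (is.null(colnames(ct)) || anyDuplicated(colnames(ct)))
    stop("`ct` must have unique colnames (sample IDs)")
  if (!is.character(reference_gene) || length(reference_gene) != 1L)
    stop("`reference_gene` must be a single gene symbol")
  if (!reference_gene %in% rownames(ct))
    stop("reference gene '", reference_gene, "' not found in the Ct matrix")
  if (any(is.infinite(ct)))
    stop("Ct values must be finite where present")
  structure(list(ct = ct, reference_gene = reference_gene),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("Ct expression matrix:", nrow(x$ct), "genes x", ncol(x$ct), "samples\n")
  cat("Reference gene:", x$reference_gene, "\n")
  cat("Missing cells:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' Delta-Ct normalisation
#'
#' Normalises each gene's Ct against the reference gene within every
#' sample: `dCt[g, s] = Ct[g, s] - Ct[reference, s]`. Higher delta-Ct means
#' lower expression. The reference row is removed from the result.
#'
#' @param expr A [ct_matrix()].
#' @return An object of class `dct_matrix` with fields `dct` (numeric
#'   matrix, cycles), `reflected` (`FALSE`: raw delta-Ct orientation) and
#'   `reference_gene`. A sample whose reference Ct is missing has all-`NA`
#'   delta-Ct and triggers a warning.
#' @export
delta_ct <- function(expr) {
  if (!inherits(expr, "ct_matrix")) stop("`expr` must be a `ct_matrix`")
  ref <- expr$ct[expr$reference_gene, ]
  dct <- sweep(expr$ct, 2L, ref, "-")
  dct <- dct[setdiff(rownames(expr$ct), expr$reference_gene), , drop = FALSE]
  bad <- is.na(ref)
  if (any(bad)) {
    dct[, bad] <- NA_real_
    warning(sum(bad), " sample(s) have missing reference Ct; ",
            "their delta-Ct values are all NA")
  }
  structure(list(dct = dct, reflected = FALSE,
                 reference_gene = expr$reference_gene),
            class = "dct_matrix")
}

#' Reflect a delta-Ct matrix
#'
#' Flips the sign of every delta-Ct value so that larger numbers mean
#' greater expression (the `-dCt` orientation used for regression and
#' correlation analyses). Reflecting twice restores the original matrix.
#'
#' @param x A `dct_matrix`.
#' @return The reflected `dct_matrix` with its `reflected` flag toggled.
#' @export
reflect <- function(x) {
  if (!inherits(x, "dct_matrix")) stop("`x` must be a `dct_matrix`")
  x$dct <- -x$dct
  x$reflected <- !x$reflected
  x
}

#' @export
print.dct_matrix <- function(x, ...) {
  cat(if (x$reflected) "Reflected delta-Ct" else "Delta-Ct", "matrix:",
      nrow(x$dct), "genes x", ncol(x$dct), "samples\n")
  invisible(x)
}

# delta-Ct values in the raw (unreflected) orientation
raw_dct <- function(x) if (x$reflected) -x$dct else x$dct

#' Relative expression from delta-Ct
#'
#' Converts delta-Ct to the relative-expression scale, `2^(-dCt)`:
#' strictly positive and halving with every extra cycle.
#'
#' @param dct Numeric vector/matrix of delta-Ct values (raw orientation),
#'   or a `dct_matrix`. `NA` propagates.
#' @return Relative expression on the same shape as the input.
#' @export
relative_expression <- function(dct) {
  if (inherits(dct, "dct_matrix")) dct <- raw_dct(dct)
  if (!is.numeric(dct)) stop("`dct` must be numeric")
  2^(-dct)
}

#' Between-group fold difference of expression
#'
#' Contrasts mean delta-Ct between two groups and expresses the result as
#' a fold difference `FD = 2^(-ddCt)` with `ddCt = mean(dCt_a) -
#' mean(dCt_b)`: `FD > 1` means group *a* expresses more than group *b*.
#' The confidence interval is computed on the ddCt scale and then
#' exponentiated.
#'
#' @param group_a,group_b Numeric vectors of delta-Ct values (raw
#'   orientation, cycles); `NA` dropped. Each group needs at least two
#'   non-missing values.
#' @param method `"welch"` (default, unequal-variance t), `"pooled"`
#'   (equal-variance t), or `"tukey"` (Tukey honest-significant-difference
#'   critical value in the context of a one-way ANOVA over `context`).
#' @param context For `method = "tukey"`: a list of *all* group samples in
#'   the ANOVA (must contain at least `group_a` and `group_b` plus any
#'   further groups); the mean square error and studentised-range critical
#'   value come from this ANOVA.
#' @param conf Confidence level (default 0.95).
#' @param groups Length-2 character vector of group labels.
#' @return Object of class `fold_difference` with fields `estimate`,
#'   `ci_low`, `ci_high` (folds), `delta_delta_ct` (cycles), `p_value`,
#'   `method`, `groups`, `n`.
#' @export
fold_difference <- function(group_a, group_b,
                            method = c("welch", "pooled", "tukey"),
                            context = NULL, conf = 0.95,
                            groups = c("a", "b")) {
  method <- match.arg(method)
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 non-missing delta-Ct values")
  ddct <- mean(a) - mean(b)

  if (method %in% c("welch", "pooled")) {
    tt <- t.test(a, b, var.equal = (method == "pooled"), conf.level = conf)
    ci_ddct <- as.numeric(tt$conf.int)
    p <- tt$p.value
  } else {
    if (is.null(context)) stop("`method = \"tukey\"` requires `context`")
    context <- lapply(context, function(v) v[!is.na(v)])
    k <- length(context)
    if (k < 3L) stop("Tukey context requires at least 3 groups")
    values <- unlist(context, use.names = FALSE)
    fac <- factor(rep.int(seq_len(k), lengths(context)))
    fit <- aov(values ~ fac)
    mse <- sum(fit$residuals^2) / fit$df.residual
    se <- sqrt(mse / 2 * (1 / length(a) + 1 / length(b)))
    crit <- qtukey(conf, k, fit$df.residual)
    ci_ddct <- ddct + c(-1, 1) * crit * se
    p <- ptukey(abs(ddct) / se, k, fit$df.residual, lower.tail = FALSE)
  }

  ci <- sort(2^(-ci_ddct))
  structure(list(estimate = 2^(-ddct), ci_low = ci[1L], ci_high = ci[2L],
                 delta_delta_ct = ddct, p_value = p, method = method,
                 conf = conf, groups = groups,
                 n = c(length(a), length(b))),
            class = "fold_difference")
}

#' @export
print.fold_difference <- function(x, digits = 3L, ...) {
  cat(sprintf("Fold difference (%s vs %s): %.*g (%.0f%% CI %.*g to %.*g), p=%.3g\n",
              x$groups[1L], x$groups[2L], digits, x$estimate, 100 * x$conf,
              digits, x$ci_low, digits, x$ci_high, x$p_value))
  cat(sprintf("  ddCt = %.*g cycles; n = %d/%d; %s\n",
              digits, x$delta_delta_ct, x$n[1L], x$n[2L], x$method))
  invisible(x)
}
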
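#' Stuart-Maxwell test of marginal homogeneity
#'
#' Tests whether the marginal category distribution changed between two
#' paired assessments (e.g. number of clinical classification criteria at
#' baseline versus follow-up). For a square k x k table of paired counts
#' the statistic is `d' S^- d`, where `d` holds the row-minus-column
#' marginal differences with one category dropped and `S` the corresponding
#' covariance matrix (`S_ii = row_i + col_i - 2 n_ii`,
#' `S_ij = -(n_ij + n_ji)`). For k = 2 this is McNemar's test without
#' continuity correction, `(b - c)^2 / (b + c)`.
#'
#' The dropped category is the one with the smallest combined marginal
#' sum, which keeps `S` invertible in the presence of structural zeros;
#' if `S` is still singular a Moore-Penrose generalised inverse is used
#' and the degrees of freedom are the rank of `S`.
#'
#' @param counts Square numeric matrix of non-negative integer counts;
#'   `counts[i, j]` = subjects in category `i` at baseline and `j` at
#'   follow-up.
#' @return An object of class `htest` with the chi-squared `statistic`,
#'   degrees of freedom `parameter` and `p.value`.
#' @export
stuart_maxwell <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k != ncol(counts) || k < 2L) stop("`counts` must be square, k >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must hold non-negative integers")
  dname <- deparse(substitute(counts))

  off_total <- sum(counts) - sum(diag(counts))
  if (off_total == 0) {
    warning("no off-diagonal counts; marginal homogeneity holds trivially")
    stat <- 0; df <- k - 1L
  } else {
    d <- rowSums(counts) - colSums(counts)
    S <- -(counts + t(counts))
    diag(S) <- rowSums(counts) + colSums(counts) - 2 * diag(counts)
    drop <- which.min(rowSums(counts) + colSums(counts))[1L]
    d <- d[-drop]
    S <- S[-drop, -drop, drop = FALSE]
    qrS <- qr(S)
    if (qrS$rank == ncol(S)) {
      stat <- as.numeric(t(d) %*% solve(S, d))
      df <- k - 1L
    } else {
      stat <- as.numeric(t(d) %*% MASS::ginv(S) %*% d)
      df <- qrS$rank
    }
  }
  structure(list(statistic = c("chi-squared" = stat),
                 parameter = c(df = df),
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = "Stuart-Maxwell test of marginal homogeneity",
                 data.name = dname),
            class = "htest")
}

#' One-way ANOVA with pairwise Tukey contrasts
#'
#' Compares a continuous variable (typically a delta-Ct score) across two
#' or more groups with a one-way F test, followed by Tukey
#' honest-significant-difference pairwise comparisons.
#'
#' @param groups Named list of numeric vectors, one per group; `NA`
#'   dropped; each group needs >= 2 values.
#' @param conf Confidence level for the Tukey intervals.
#' @return Object of class `anova_tukey`: `statistic` (F), `df`,
#'   `p.value`, and `tukey`, a data frame of pairwise differences with
#'   adjusted p-values and intervals on the input scale.
#' @export
anova_tukey <- function(groups, conf = 0.95) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (sum(tapply(values, fac, var)) <= .Machine$double.eps)
    stop("zero within-group variance in every group")
  fit <- aov(values ~ fac)
  tab <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = conf)$fac
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(statistic = c(F = tab$`F value`[1L]),
                 df = c(tab$Df[1L], tab$Df[2L]),
                 p.value = tab$`Pr(>F)`[1L],
                 tukey = tukey, conf = conf,
                 method = "One-way ANOVA with Tukey HSD"),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, digits = 4L, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.*g, p = %.3g\n",
              x$df[1L], x$df[2L], digits, x$statistic, x$p.value))
  cat("Tukey pairwise contrasts:\n")
  print(x$tukey, digits = digits)
  invisible(x)
}

#' Kendall's tau-b correlation
#'
#' Rank correlation with tie correction in both margins, suitable for
#' ordinal variables (e.g. counts of positive ANA specificities). The
#' p-value uses the normal approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return An `htest` with the tau-b estimate, z statistic and p-value.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("tau-b is undefined for a constant vector")
  out <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  out$method <- "Kendall's tau-b correlation (normal approximation)"
  names(out$estimate) <- "tau-b"
  out
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test for association between two binary variables,
#' summing hypergeometric probabilities no larger than the observed
#' table's.
#'
#' @param counts 2 x 2 matrix of non-negative integer counts.
#' @return An `htest`. An empty row or column margin yields `p = 1` with
#'   a warning.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("`counts` must be 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must hold non-negative integers")
  dname <- deparse(substitute(counts))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("empty margin: association is undefined, p = 1")
    return(structure(list(p.value = 1,
                          estimate = c("odds ratio" = NA_real_),
                          method = "Fisher's exact test",
                          alternative = "two.sided", data.name = dname),
                     class = "htest"))
  }
  out <- fisher.test(counts)
  out$data.name <- dname
  out
}

#' Pearson product-moment correlation
#'
#' Linear correlation with a t-based p-value, used for continuous
#' variables without ties (e.g. complement C4 against an interferon
#' score).
#'
#' @param x,y Numeric vectors of equal length >= 3, finite.
#' @return An `htest` from the correlation test.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation is undefined for a constant vector")
  cor.test(x, y, method = "pearson")
}
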
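#' Principal-axis factor analysis of ISG expression
#'
#' Reduces the interferon-stimulated genes to a small number of latent
#' factors by principal-axis factoring of the gene-gene correlation matrix
#' of reflected delta-Ct, followed by varimax rotation (for two or more
#' factors). Communalities are initialised at the squared multiple
#' correlations and iterated to convergence.
#'
#' Only samples with complete expression are used for the correlation
#' matrix; constant (zero-variance) genes are excluded with a warning.
#'
#' @param dct A `dct_matrix` (either orientation; correlations are
#'   computed on the reflected scale).
#' @param n_factors Number of factors to extract (default 2).
#' @param max_iter,tol Iteration control for the communality loop.
#' @return Object of class `factor_model`: `loadings` (genes x factors),
#'   `n_factors`, `variance_explained` (proportion of total variance per
#'   rotated factor), `cumulative_variance`, `eigenvalues` (of the
#'   reduced correlation matrix at convergence — the unrotated factor
#'   strengths, useful for judging dimensionality), `communalities`,
#'   `n_samples`, `dropped_genes`.
#' @export
fit_factor_model <- function(dct, n_factors = 2L, max_iter = 200L,
                             tol = 1e-7) {
  if (!inherits(dct, "dct_matrix")) stop("`dct` must be a `dct_matrix`")
  x <- t(-raw_dct(dct))                       # samples x genes, reflected
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < n_factors + 2L)
    stop("need at least n_factors + 2 complete samples (have ",
         nrow(x), ")")
  vars <- apply(x, 2L, var)
  dropped <- colnames(x)[vars <= .Machine$double.eps]
  if (length(dropped)) {
    warning("excluding constant gene(s): ", paste(dropped, collapse = ", "))
    x <- x[, vars > .Machine$double.eps, drop = FALSE]
  }
  p <- ncol(x)
  if (p < 3L * n_factors)
    stop("need at least 3 genes per factor (have ", p, ")")

  R <- cor(x)
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) apply(abs(R - diag(p)), 1L, max))
  h2 <- pmin(pmax(smc, 0.05), 0.995)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  eigenvalues <- e$values
  if (n_factors > 1L) L <- stats::varimax(L)$loadings[, , drop = FALSE]
  L <- unclass(L)
  # orient each factor so most genes load positively, order by variance
  for (j in seq_len(n_factors))
    if (sum(L[, j]) < 0) L[, j] <- -L[, j]
  ve <- colSums(L^2) / p
  ord <- order(ve, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ve <- ve[ord]
  dimnames(L) <- list(colnames(x), paste0("F", seq_len(n_factors)))
  structure(list(loadings = L, n_factors = n_factors,
                 variance_explained = ve,
                 cumulative_variance = cumsum(ve),
                 eigenvalues = eigenvalues,
                 communalities = setNames(h2, colnames(x)),
                 n_samples = nrow(x), dropped_genes = dropped),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Principal-axis factor model:", x$n_factors, "factors,",
      nrow(x$loadings), "genes,", x$n_samples, "samples\n")
  cat("Variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      sprintf("(cumulative %.1f%%)\n", 100 * max(x$cumulative_variance)))
  invisible(x)
}

#' Gene partition for the two interferon scores
#'
#' A fixed assignment of ISGs to the Score-A and Score-B gene sets. Use
#' this constructor to supply a pre-specified partition (the primary
#' operating mode, mirroring published gene sets), or derive one from data
#' with [assign_genes()].
#'
#' @param score_a,score_b Character vectors of gene symbols (disjoint,
#'   non-empty).
#' @param unassigned Genes in neither set (default none).
#' @param loading_threshold Minimum absolute loading used to build the
#'   partition, if derived from a factor model (`NA` for fixed lists).
#' @return Object of class `gene_partition`.
#' @export
gene_partition <- function(score_a, score_b, unassigned = character(),
                           loading_threshold = NA_real_) {
  score_a <- as.character(score_a); score_b <- as.character(score_b)
  unassigned <- as.character(unassigned)
  all <- c(score_a, score_b, unassigned)
  if (anyDuplicated(all))
    stop("gene sets must be disjoint with no duplicates")
  if (!length(score_a) || !length(score_b))
    stop("both score gene sets must be non-empty")
  structure(list(score_a_genes = score_a, score_b_genes = score_b,
                 unassigned = unassigned,
                 loading_threshold = loading_threshold),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat("Gene partition: Score-A", length(x$score_a_genes), "genes;",
      "Score-B", length(x$score_b_genes), "genes;",
      length(x$unassigned), "unassigned\n")
  invisible(x)
}

#' Assign genes to scores from a two-factor model
#'
#' Each gene goes to the factor on which its absolute loading is largest,
#' provided that loading reaches `loading_threshold`; otherwise it is left
#' unassigned. Exact ties go to Score-A.
#'
#' @param model A [fit_factor_model()] result with exactly two factors.
#' @param loading_threshold Minimum absolute loading (default 0.4).
#' @return A [gene_partition()].
#' @export
assign_genes <- function(model, loading_threshold = 0.4) {
  if (!inherits(model, "factor_model")) stop("`model` must be a `factor_model`")
  if (model$n_factors != 2L) stop("gene assignment requires exactly 2 factors")
  L <- abs(model$loadings)
  top <- ifelse(L[, 1L] >= L[, 2L], 1L, 2L)     # tie -> factor A
  ok <- pmax(L[, 1L], L[, 2L]) >= loading_threshold
  genes <- rownames(L)
  gene_partition(score_a = genes[ok & top == 1L],
                 score_b = genes[ok & top == 2L],
                 unassigned = genes[!ok],
                 loading_threshold = loading_threshold)
}

#' Per-sample interferon scores
#'
#' The score of a sample on each gene set is the median delta-Ct of the
#' set's observed genes (even cardinality: mean of the central pair).
#' A score is `NA` when fewer than `min_genes` of the set's genes are
#' observed in that sample.
#'
#' @param dct A `dct_matrix` (either orientation; the orientation is
#'   recorded in the result).
#' @param partition A [gene_partition()]. Genes absent from `dct` are
#'   ignored with a warning.
#' @param min_genes Minimum observed genes per set, a length-2 vector (A,
#'   B) or single value; default `ceiling(set size / 2)`.
#' @return Object of class `ifn_scores`: a data frame with columns
#'   `sample`, `score_a`, `score_b`, `n_a`, `n_b` and attribute
#'   `reflected`.
#' @export
compute_scores <- function(dct, partition, min_genes = NULL) {
  if (!inherits(dct, "dct_matrix")) stop("`dct` must be a `dct_matrix`")
  if (!inherits(partition, "gene_partition"))
    stop("`partition` must be a `gene_partition`")
  sets <- list(a = partition$score_a_genes, b = partition$score_b_genes)
  present <- lapply(sets, intersect, x = rownames(dct$dct))
  missing_genes <- sum(lengths(sets)) - sum(lengths(present))
  if (missing_genes > 0L)
    warning(missing_genes, " partition gene(s) absent from the matrix")
  if (!all(lengths(present) > 0L))
    stop("a score gene set has no genes present in the matrix")
  if (is.null(min_genes)) min_genes <- ceiling(lengths(present) / 2)
  min_genes <- rep_len(min_genes, 2L)

  one <- function(genes, floor_n) {
    sub <- dct$dct[genes, , drop = FALSE]
    n_used <- colSums(!is.na(sub))
    score <- apply(sub, 2L, median, na.rm = TRUE)
    score[n_used < floor_n] <- NA_real_
    list(score = score, n = n_used)
  }
  a <- one(present$a, min_genes[1L])
  b <- one(present$b, min_genes[2L])
  n_low <- sum(is.na(a$score) & a$n > 0) + sum(is.na(b$score) & b$n > 0)
  if (n_low > 0L)
    warning(n_low, " score(s) set to NA: fewer observed genes than the ",
            "minimum")
  out <- data.frame(sample = colnames(dct$dct),
                    score_a = unname(a$score), score_b = unname(b$score),
                    n_a = unname(a$n), n_b = unname(b$n),
                    stringsAsFactors = FALSE)
  attr(out, "reflected") <- dct$reflected
  class(out) <- c("ifn_scores", "data.frame")
  out
}

#' Classify samples against a delta-Ct cutoff
#'
#' A sample is *positive* (high interferon, at risk of progression) when
#' its score, in raw delta-Ct units, is less than or equal to the cutoff
#' (lower delta-Ct = more expression). Reflected scores are converted back
#' before comparison. `NA` scores are left unclassified (`NA`).
#'
#' @param scores An [compute_scores()] result, or a numeric vector of
#'   scores in raw delta-Ct units.
#' @param cutoff Finite delta-Ct threshold (e.g. 5.01).
#' @param which `"B"` (default) or `"A"`: which score to classify when
#'   `scores` is an `ifn_scores` object.
#' @return Factor with levels `negative`, `positive`; `NA` = unclassified.
#' @export
classify_scores <- function(scores, cutoff, which = c("B", "A")) {
  which <- match.arg(which)
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  if (inherits(scores, "ifn_scores")) {
    v <- if (which == "A") scores$score_a else scores$score_b
    if (isTRUE(attr(scores, "reflected"))) v <- -v
  } else v <- as.numeric(scores)
  factor(ifelse(v <= cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}
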
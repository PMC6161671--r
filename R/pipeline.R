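#' Read a Ct matrix from CSV
#'
#' Expects a header row whose first column is named `gene`, remaining
#' columns being sample IDs; cells hold Ct values, empty cells mark
#' missing measurements.
#'
#' @param path CSV file path.
#' @param reference_gene Reference gene symbol (must appear in the file).
#' @return A [ct_matrix()].
#' @export
read_ct_matrix <- function(path, reference_gene) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!ncol(raw) >= 2L || names(raw)[1L] != "gene")
    stop("malformed Ct CSV: first column must be named 'gene'")
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric Ct cell at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  rownames(num) <- genes
  ct_matrix(num, reference_gene)
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [read_ct_matrix()]; missing cells are written empty.
#'
#' @param expr A [ct_matrix()].
#' @param path Output CSV path.
#' @export
write_ct_matrix <- function(expr, path) {
  if (!inherits(expr, "ct_matrix")) stop("`expr` must be a `ct_matrix`")
  df <- data.frame(gene = rownames(expr$ct), expr$ct,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a gene partition as JSON
#'
#' The on-disk format is `{"score_a": [genes...], "score_b": [genes...]}`
#' with an optional `"unassigned"` array.
#'
#' @param path JSON file path.
#' @return [read_partition()]: a [gene_partition()].
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$score_a) || is.null(obj$score_b))
    stop("partition JSON must contain 'score_a' and 'score_b' arrays")
  gene_partition(obj$score_a, obj$score_b,
                 unassigned = obj$unassigned %||% character())
}

#' @rdname read_partition
#' @param partition A [gene_partition()].
#' @export
write_partition <- function(partition, path) {
  if (!inherits(partition, "gene_partition"))
    stop("`partition` must be a `gene_partition`")
  jsonlite::write_json(list(score_a = partition$score_a_genes,
                            score_b = partition$score_b_genes,
                            unassigned = partition$unassigned),
                       path, pretty = TRUE)
  invisible(path)
}

#' Read or write per-sample scores as CSV
#'
#' Columns: `sample`, `score_a`, `score_b`, `n_a`, `n_b`.
#'
#' @param scores An [compute_scores()] result.
#' @param path CSV file path.
#' @param reflected Orientation flag recorded when reading (raw delta-Ct
#'   by default).
#' @export
write_scores <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path, reflected = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "score_a", "score_b", "n_a", "n_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scores CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  attr(df, "reflected") <- reflected
  class(df) <- c("ifn_scores", "data.frame")
  df
}

#' Read sample metadata from CSV
#'
#' Validates that the required columns are present and that `group`
#' levels are recognised; reports the offending column by name otherwise.
#'
#' @param path CSV file path.
#' @param required Column names that must be present.
#' @return Data frame.
#' @export
read_metadata <- function(path, required = c("sample", "group",
                                             "progression")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  if ("group" %in% names(df) &&
      !all(df$group %in% c("hc", "at_risk", "sle")))
    stop("column 'group' must contain only hc / at_risk / sle")
  df
}

#' Run the end-to-end prognostic analysis
#'
#' Executes the whole pipeline on a cohort (by default a synthetic one
#' generated from `config`): delta-Ct normalisation, gene partitioning
#' (factor-analytic or pre-specified), per-sample scoring, group fold
#' differences with ANOVA context, ROC analysis of both scores with
#' Youden and rule-in operating points, and the multiply-imputed
#' penalised prognostic model. Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built cohort (a [simulate_cohort()] result,
#'   or a list with `expression` = [ct_matrix()] and `meta` in the same
#'   layout).
#' @param partition `"fit"` (derive the two-score partition by factor
#'   analysis), `"truth"` (use the generative partition, synthetic
#'   cohorts only), or a [gene_partition()].
#' @param min_specificity Specificity floor for the rule-in cutoff.
#' @param fixed_cutoff Optional fixed delta-Ct cutoff for Score-B, also
#'   evaluated (e.g. 5.01).
#' @param m,cycles,alpha Settings passed to [fit_prognostic()].
#' @param out_dir Optional directory; when given, the report JSON and
#'   tidy CSVs are written there (partial outputs are removed on
#'   failure).
#' @return Object of class `analysis_report` (a named list of sections
#'   with a `provenance` record).
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         partition = "fit", min_specificity = 0.8,
                         fixed_cutoff = NULL, m = config$m, cycles = 10L,
                         alpha = 0.10, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  meta <- cohort$meta
  dct <- suppressWarnings(delta_ct(cohort$expression))

  if (inherits(partition, "gene_partition")) {
    part <- partition
  } else if (identical(partition, "truth")) {
    if (is.null(cohort$truth))
      stop("partition = 'truth' requires a synthetic cohort")
    part <- cohort$truth$partition
  } else if (identical(partition, "fit")) {
    model <- fit_factor_model(dct, n_factors = 2L)
    part <- assign_genes(model)
  } else stop("`partition` must be 'fit', 'truth' or a gene_partition")

  scores <- suppressWarnings(compute_scores(dct, part))
  idx <- match(meta$sample, scores$sample)
  ar <- meta$group == "at_risk"
  prog <- meta$progression == 1L

  by_group <- function(v) split(v[idx], meta$group)[c("hc", "at_risk",
                                                      "sle")]
  ga <- by_group(scores$score_a)
  gb <- by_group(scores$score_b)
  anova_a <- anova_tukey(ga)
  anova_b <- anova_tukey(gb)
  fd <- list(
    a_at_risk_vs_hc = fold_difference(ga$at_risk, ga$hc, method = "tukey",
                                      context = ga,
                                      groups = c("at_risk", "hc")),
    a_sle_vs_hc = fold_difference(ga$sle, ga$hc, method = "tukey",
                                  context = ga, groups = c("sle", "hc")),
    b_at_risk_vs_hc = fold_difference(gb$at_risk, gb$hc, method = "tukey",
                                      context = gb,
                                      groups = c("at_risk", "hc")),
    b_sle_vs_hc = fold_difference(gb$sle, gb$hc, method = "tukey",
                                  context = gb, groups = c("sle", "hc")),
    a_prog_vs_nonprog = fold_difference(
      scores$score_a[idx][ar & prog], scores$score_a[idx][ar & !prog],
      groups = c("progressors", "non-progressors")),
    b_prog_vs_nonprog = fold_difference(
      scores$score_b[idx][ar & prog], scores$score_b[idx][ar & !prog],
      groups = c("progressors", "non-progressors")))

  roc_a <- ifn_roc(scores$score_a[idx][ar], meta$progression[ar])
  roc_b <- ifn_roc(scores$score_b[idx][ar], meta$progression[ar])
  roc <- list(score_a = roc_a, score_b = roc_b,
              comparison = compare_auc_paired(roc_b, roc_a))
  cutoffs <- list(youden = youden_cutoff(roc_b),
                  rule_in = rule_in_cutoff(roc_b, min_specificity))
  if (!is.null(fixed_cutoff)) {
    lab <- classify_scores(scores[idx, ][ar, ], fixed_cutoff, which = "B")
    truth <- factor(ifelse(prog[ar], "positive", "negative"),
                    levels = c("negative", "positive"))
    ok <- !is.na(lab)
    cutoffs$fixed <- list(
      cutoff = fixed_cutoff,
      metrics = diagnostics(
        sum(lab == "positive" & truth == "positive" & ok),
        sum(lab == "positive" & truth == "negative" & ok),
        sum(lab == "negative" & truth == "positive" & ok),
        sum(lab == "negative" & truth == "negative" & ok)))
  }

  model_tab <- cohort_table(cohort, scores)
  prognosis <- fit_prognostic(model_tab, m = m, cycles = cycles,
                              alpha = alpha, seed = config$seed)

  report <- structure(list(
    partition = part, scores = scores, anova = list(score_a = anova_a,
                                                    score_b = anova_b),
    fold_differences = fd, roc = roc, cutoffs = cutoffs,
    prognosis = prognosis,
    provenance = list(seed = config$seed, m = m, cycles = cycles,
                      alpha = alpha,
                      package_version = as.character(
                        packageVersion("ifnprog")))),
    class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Interferon-score prognostic analysis ==\n\n")
  print(x$partition)
  cat(sprintf("\nScore-A ANOVA across groups: F = %.2f, p = %.3g\n",
              x$anova$score_a$statistic, x$anova$score_a$p.value))
  cat(sprintf("Score-B ANOVA across groups: F = %.2f, p = %.3g\n",
              x$anova$score_b$statistic, x$anova$score_b$p.value))
  cat("\nFold differences:\n")
  for (nm in names(x$fold_differences)) {
    cat(sprintf("  [%s] ", nm)); print(x$fold_differences[[nm]])
  }
  cat(sprintf("\nROC (progression): Score-B AUC %.2f (%.2f to %.2f) vs Score-A AUC %.2f (%.2f to %.2f); DeLong chi2 = %.2f, p = %.3g\n",
              x$roc$score_b$auc, x$roc$score_b$auc_ci[1L],
              x$roc$score_b$auc_ci[2L], x$roc$score_a$auc,
              x$roc$score_a$auc_ci[1L], x$roc$score_a$auc_ci[2L],
              x$roc$comparison$statistic, x$roc$comparison$p.value))
  cat("\n"); print(x$cutoffs$youden)
  cat("\n"); print(x$cutoffs$rule_in)
  cat("\n"); print(x$prognosis)
  invisible(x)
}

# serialise the machine-readable parts of a report
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) { unlink(written); stop(e) }
  tryCatch({
    f <- file.path(out_dir, "scores.csv")
    write_scores(report$scores, f); written <- c(written, f)
    f <- file.path(out_dir, "partition.json")
    write_partition(report$partition, f); written <- c(written, f)
    f <- file.path(out_dir, "roc_score_b.csv")
    write.csv(report$roc$score_b$thresholds, f, row.names = FALSE)
    written <- c(written, f)
    fd_tab <- do.call(rbind, lapply(names(report$fold_differences),
      function(nm) {
        x <- report$fold_differences[[nm]]
        data.frame(comparison = nm, estimate = x$estimate,
                   ci_low = x$ci_low, ci_high = x$ci_high,
                   p = x$p_value, method = x$method)
      }))
    f <- file.path(out_dir, "fold_differences.csv")
    write.csv(fd_tab, f, row.names = FALSE); written <- c(written, f)
    cut_json <- lapply(report$cutoffs, function(co) {
      met <- co$metrics
      list(cutoff = co$cutoff,
           metrics = setNames(as.list(met$estimate), met$metric))
    })
    mv <- report$prognosis$multivariable
    f <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      auc = list(score_a = report$roc$score_a$auc,
                 score_b = report$roc$score_b$auc,
                 comparison_p = report$roc$comparison$p.value),
      cutoffs = cut_json,
      multivariable = mv[, c("term", "or", "or_low", "or_high",
                             "p.value")],
      penalized = report$prognosis$penalized,
      provenance = report$provenance),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }, error = on_fail)
  invisible(out_dir)
}
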
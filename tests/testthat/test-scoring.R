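test_that("two simulated orthogonal factors are recovered", {
  d <- simulate_two_factor(n = 200, seed = 1)
  m <- fit_factor_model(d, n_factors = 2)
  # the two factors carry >= 80% of the variance in this design
  expect_gte(max(m$cumulative_variance), 0.80)
  part <- assign_genes(m, loading_threshold = 0.4)
  truth_a <- paste0("G", 1:15)
  truth_b <- paste0("G", 16:30)
  # recovered sets match the generative sets up to factor order
  hits <- max(
    length(intersect(part$score_a_genes, truth_a)) +
      length(intersect(part$score_b_genes, truth_b)),
    length(intersect(part$score_a_genes, truth_b)) +
      length(intersect(part$score_b_genes, truth_a)))
  expect_gte(hits / 30, 0.9)
  expect_length(part$unassigned, 30 - hits)
})

test_that("a single-factor structure leaves the second factor weak", {
  d <- simulate_two_factor(n = 200, genes_per_factor = 15, n_factors = 1,
                           seed = 2)
  m <- fit_factor_model(d, n_factors = 2)
  # dimensionality is judged on the unrotated factor strengths
  # (varimax deliberately spreads variance across rotated factors)
  ev <- pmax(m$eigenvalues, 0)
  expect_lt(ev[2L] / sum(ev), 0.10)
})

test_that("loadings are invariant to duplicating every sample", {
  d <- simulate_two_factor(n = 80, seed = 3)
  d2 <- d
  d2$dct <- cbind(d$dct, d$dct)
  colnames(d2$dct) <- paste0("S", seq_len(ncol(d2$dct)))
  m1 <- fit_factor_model(d, n_factors = 2)
  m2 <- fit_factor_model(d2, n_factors = 2)
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-10)
})

test_that("constant genes are dropped with a warning, small data error", {
  d <- simulate_two_factor(n = 30, seed = 4)
  d$dct <- rbind(d$dct, FLAT = rep(1, ncol(d$dct)))
  expect_warning(m <- fit_factor_model(d, n_factors = 2), "FLAT")
  expect_false("FLAT" %in% rownames(m$loadings))
  tiny <- d
  tiny$dct <- tiny$dct[, 1:3]
  expect_error(fit_factor_model(tiny, n_factors = 2), "complete samples")
})

test_that("gene assignment follows the maximal loading above threshold", {
  m <- structure(list(
    loadings = rbind(g1 = c(0.9, 0.1), g2 = c(0.2, 0.25),
                     g3 = c(0.3, 0.8), g4 = c(0.5, 0.5)),
    n_factors = 2L), class = "factor_model")
  p <- assign_genes(m, loading_threshold = 0.4)
  expect_identical(p$score_a_genes, c("g1", "g4"))  # tie goes to A
  expect_identical(p$score_b_genes, "g3")
  expect_identical(p$unassigned, "g2")
})

test_that("scores are set medians with even/odd handling", {
  dct <- structure(list(dct = rbind(
    g1 = c(4, 2), g2 = c(5, 4), g3 = c(6, 6), g4 = c(NA, 8)),
    reflected = FALSE), class = "dct_matrix")
  colnames(dct$dct) <- c("S1", "S2")
  part <- gene_partition(c("g1", "g2", "g3", "g4"), "placeholder")
  part$score_b_genes <- c("g1", "g2")  # reuse g1/g2 as a 2-gene set
  s <- compute_scores(dct, part, min_genes = c(3, 2))
  expect_equal(s$score_a, c(5, 5))   # odd median {4,5,6}; even {2,4,6,8}
  expect_equal(s$n_a, c(3, 4))
  expect_equal(s$score_b, c(4.5, 3))
})

test_that("median equals the 50th percentile of a sorting oracle", {
  set.seed(10)
  for (n in c(7, 12)) {
    v <- rnorm(n)
    srt <- sort(v)
    oracle <- if (n %% 2) srt[(n + 1) / 2] else
      mean(srt[n / 2 + 0:1])
    dct <- structure(list(dct = matrix(v, ncol = 1,
                                       dimnames = list(paste0("g", 1:n),
                                                       "S1")),
                          reflected = FALSE), class = "dct_matrix")
    part <- gene_partition(paste0("g", 1:n), "placeholder")
    part$score_b_genes <- "g1"
    s <- compute_scores(dct, part, min_genes = 1)
    expect_identical(s$score_a, oracle)
  }
})

test_that("too few observed genes yields NA score with warning", {
  dct <- structure(list(dct = rbind(g1 = c(4, NA), g2 = c(5, NA),
                                    g3 = c(6, 2), g4 = c(1, 3)),
                        reflected = FALSE), class = "dct_matrix")
  colnames(dct$dct) <- c("S1", "S2")
  part <- gene_partition(c("g1", "g2", "g3"), "g4")
  expect_warning(s <- compute_scores(dct, part, min_genes = c(2, 1)),
                 "fewer observed genes")
  expect_true(is.na(s$score_a[2L]))
  expect_false(is.na(s$score_b[2L]))
})

test_that("scores are invariant to gene and sample permutation, and a
           per-sample shift moves both scores by that constant", {
  d <- simulate_two_factor(n = 40, seed = 5)
  part <- gene_partition(paste0("G", 1:15), paste0("G", 16:30))
  s <- compute_scores(d, part)
  perm <- d
  perm$dct <- perm$dct[sample(nrow(perm$dct)), sample(ncol(perm$dct))]
  sp <- compute_scores(perm, part)
  idx <- match(s$sample, sp$sample)
  expect_equal(s$score_a, sp$score_a[idx])
  expect_equal(s$score_b, sp$score_b[idx])
  shifted <- d
  shifted$dct[, 1L] <- shifted$dct[, 1L] + 2.5
  ss <- compute_scores(shifted, part)
  expect_equal(ss$score_a[1L], s$score_a[1L] + 2.5)
  expect_equal(ss$score_b[1L], s$score_b[1L] + 2.5)
})

test_that("classification against a delta-Ct cutoff is inclusive", {
  lab <- classify_scores(c(5.01, 5.02, NA, 3.9), 5.01)
  expect_identical(as.character(lab),
                   c("positive", "negative", NA, "positive"))
  # reflected scores are converted back before comparison
  s <- data.frame(sample = "x", score_a = -4, score_b = -5.01,
                  n_a = 15L, n_b = 15L)
  attr(s, "reflected") <- TRUE
  class(s) <- c("ifn_scores", "data.frame")
  expect_identical(as.character(classify_scores(s, 5.01, "B")),
                   "positive")
  expect_error(classify_scores(c(1, 2), Inf), "finite")
})

test_that("partition JSON round-trips", {
  p <- gene_partition(c("a", "b"), c("c"), unassigned = "d",
                      loading_threshold = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(p, path)
  back <- read_partition(path)
  expect_identical(back$score_a_genes, p$score_a_genes)
  expect_identical(back$score_b_genes, p$score_b_genes)
  expect_identical(back$unassigned, p$unassigned)
})
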
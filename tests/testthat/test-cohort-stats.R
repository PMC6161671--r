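# independent matrix oracle for the marginal-homogeneity statistic:
# drops an arbitrary category and inverts directly
sm_oracle <- function(tab, drop = 1L) {
  k <- nrow(tab)
  d <- rowSums(tab) - colSums(tab)
  S <- -(tab + t(tab))
  diag(S) <- rowSums(tab) + colSums(tab) - 2 * diag(tab)
  as.numeric(t(d[-drop]) %*% solve(S[-drop, -drop]) %*% d[-drop])
}

test_that("non-progressor criteria transitions give chi-squared 38.1", {
  # 19 with 0 criteria at both visits, 1 gained a criterion, 41 remitted
  # from 1 to 0, 38 kept one criterion
  tab <- matrix(c(19, 1, 41, 38), 2, 2, byrow = TRUE)
  res <- stuart_maxwell(tab)
  expect_equal(unname(res$statistic), (41 - 1)^2 / 42)  # 38.095
  expect_equal(round(unname(res$statistic), 1), 38.1)
  expect_lt(res$p.value, 0.001)
  expect_equal(unname(res$parameter), 1)
})

test_that("progressor criteria transitions match the matrix oracle", {
  # all 19 progressors held 1 criterion at baseline; at 12 months 4 had
  # 2, 9 had 3 and 6 had 4 criteria
  tab <- matrix(0, 4, 4)
  tab[1, 2:4] <- c(4, 9, 6)
  res <- stuart_maxwell(tab)
  expect_equal(unname(res$statistic), sm_oracle(tab, drop = 1L))
  expect_equal(unname(res$statistic), 19.0, tolerance = 1e-12)
  expect_lt(res$p.value, 0.001)
})

test_that("Stuart-Maxwell reduces to McNemar for any 2x2 table", {
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 10), 2, 2)
    b <- tab[1, 2]; cc <- tab[2, 1]
    if (b + cc == 0) next
    expect_equal(unname(stuart_maxwell(tab)$statistic),
                 (b - cc)^2 / (b + cc))
  }
})

test_that("Stuart-Maxwell degeneracies and invariances", {
  sym <- matrix(c(5, 2, 2, 7), 2, 2)
  expect_equal(unname(stuart_maxwell(sym)$statistic), 0)
  diag_only <- diag(c(3, 4, 5))
  expect_warning(res <- stuart_maxwell(diag_only), "off-diagonal")
  expect_equal(unname(res$statistic), 0)
  # invariant to simultaneous permutation of categories
  set.seed(8)
  tab <- matrix(rpois(9, 6), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(unname(stuart_maxwell(tab[perm, perm])$statistic),
               unname(stuart_maxwell(tab)$statistic), tolerance = 1e-9)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  g <- list(a = rnorm(14, 1), b = rnorm(19, 2))
  res <- anova_tukey(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(unname(res$statistic), unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give F = 0 and Tukey p >= raw pairwise p", {
  g0 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- anova_tukey(g0)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  set.seed(6)
  g <- list(x = rnorm(10), y = rnorm(10, 0.5), z = rnorm(10, 1))
  res3 <- anova_tukey(g)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    raw <- t.test(g[[pair[1]]], g[[pair[2]]], var.equal = TRUE)$p.value
    adj <- res3$tukey$p_adj[res3$tukey$comparison ==
                              paste(pair[2], pair[1], sep = "-")]
    expect_gte(adj + 1e-9, raw)
  }
  expect_error(anova_tukey(list(a = c(1, 1), b = c(1, 1))),
               "zero within-group variance")
})

test_that("Kendall tau-b handles ties per the pair-enumeration oracle", {
  # x=(1,1,2), y=(1,2,2): C=1, D=0, one tie in each margin ->
  # tau-b = 1 / sqrt((3-1)(3-1)) = 0.5
  res <- kendall_tau_b(c(1, 1, 2), c(1, 2, 2))
  expect_equal(unname(res$estimate), 0.5)
  expect_equal(unname(kendall_tau_b(1:3, 1:3)$estimate), 1)
  expect_equal(unname(kendall_tau_b(c(1, 1, 2), -c(1, 2, 2))$estimate),
               -0.5)  # antisymmetry
  expect_error(kendall_tau_b(c(1, 1, 1), 1:3), "constant")
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(res$p.value, 2 / choose(10, 5))  # 2/252
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2, 2))$p.value, 1)
  # brute force over all tables with the observed margins
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    probs <- vapply(max(0, r1 + c1 - n):min(r1, c1), function(a)
      dhyper(a, c1, n - c1, r1), numeric(1))
    obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4) + 1, 2, 2)
    expect_equal(fisher_exact(tab)$p.value, enum_p(tab),
                 tolerance = 1e-10)
  }
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)),
                 "empty margin")
  expect_equal(p0$p.value, 1)
})

test_that("Pearson correlation behaves on exact and simulated data", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(unname(pearson_r(x, 2 * x + 1)$estimate), 1)
  expect_equal(unname(pearson_r(x, -x)$estimate), -1)
  set.seed(77)
  z <- rnorm(1000)
  y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(1000)
  expect_equal(unname(pearson_r(z, y)$estimate), 0.5, tolerance = 0.05)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})
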
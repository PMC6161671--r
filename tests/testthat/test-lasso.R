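# simulated logistic data shared by several blocks
sim_logit <- function(n = 50, p = 3, beta = c(1, -0.5, 0), b0 = 0.3,
                      seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, plogis(b0 + X %*% beta))
  list(X = X, y = y)
}

test_that("at lambda >= lambda_max every slope is exactly zero (KKT)", {
  d <- sim_logit(n = 120, seed = 2)
  f <- lasso_logistic(d$X, d$y)
  expect_equal(unname(f$beta[, 1L]), rep(0, 3))
  # analytic KKT at the null model: |X'(y - ybar)|/n <= lambda
  xstd <- scale(d$X, scale = sqrt(colMeans(scale(d$X, scale = FALSE)^2)))
  grad <- abs(crossprod(xstd, d$y - mean(d$y))) / nrow(d$X)
  expect_lte(max(grad), f$lambda_max + 1e-12)
  # and the fitted intercept is the logit of the prevalence
  expect_equal(f$a0[1L], qlogis(mean(d$y)), tolerance = 1e-6)
})

test_that("lambda -> 0 recovers the Newton-Raphson MLE to 1e-5", {
  d <- sim_logit(n = 50, p = 3, seed = 3)
  f <- lasso_logistic(d$X, d$y, lambda = c(0.5, 1e-9))
  mle <- coef(glm(d$y ~ d$X, family = binomial()))
  expect_equal(unname(coef(f, s = 1e-9)), unname(mle), tolerance = 1e-5)
})

test_that("KKT conditions hold along the path", {
  d <- sim_logit(n = 150, p = 5, beta = c(1.2, -0.8, 0.4, 0, 0), seed = 4)
  f <- lasso_logistic(d$X, d$y, nlambda = 25)
  xstd <- sweep(sweep(d$X, 2, f$xm), 2, f$xs, "/")
  for (i in c(5L, 12L, 20L)) {
    lam <- f$lambda[i]
    eta <- f$a0[i] + as.numeric(d$X %*% f$beta[, i])
    grad <- as.numeric(crossprod(xstd, d$y - plogis(eta))) / nrow(d$X)
    b <- f$beta_std[, i]
    expect_true(all(abs(grad[b == 0]) <= lam + 1e-6))
    active <- b != 0
    expect_equal(grad[active], lam * sign(b[active]), tolerance = 1e-5)
  }
})

test_that("solution path agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  d <- sim_logit(n = 200, p = 4, beta = c(1, -0.7, 0.3, 0), seed = 5)
  lam <- c(0.1, 0.05, 0.02, 0.005)
  ours <- lasso_logistic(d$X, d$y, lambda = lam)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", lambda = lam,
                      standardize = TRUE, thresh = 1e-12)
  for (i in seq_along(lam)) {
    bg <- as.numeric(glmnet::coef.glmnet(g, s = lam[i], exact = TRUE,
                                         x = d$X, y = d$y))
    expect_equal(unname(coef(ours, s = lam[i])), bg, tolerance = 5e-3)
  }
})

test_that("active set is monotone-ish and df drop to zero at the top", {
  d <- sim_logit(n = 150, p = 6, beta = c(1.5, 1, 0.5, 0, 0, 0), seed = 6)
  f <- lasso_logistic(d$X, d$y, nlambda = 40)
  expect_equal(f$df[1L], 0)
  expect_gte(f$df[40L], f$df[1L])
})

test_that("LOOCV: lambda_1se >= lambda_min and null deviance limit", {
  d <- sim_logit(n = 60, p = 3, seed = 7)
  # an explicit path whose top penalty dwarfs every fold's lambda_max
  cv <- cv_lasso_logistic(d$X, d$y,
                          lambda = c(5, exp(seq(log(0.3), log(0.001),
                                                length.out = 20))))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  # at the largest penalty the model is intercept-only; its mean LOO
  # deviance matches the leave-one-out null-prevalence closed form
  n <- length(d$y)
  p_loo <- (sum(d$y) - d$y) / (n - 1)
  dev_null <- mean(-2 * (d$y * log(pmax(p_loo, 1e-8)) +
                           (1 - d$y) * log(pmax(1 - p_loo, 1e-8))))
  expect_equal(cv$cvm[1L], dev_null, tolerance = 1e-6)
})

test_that("pure-noise predictors select the null model at lambda_1se", {
  wins <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(rnorm(80 * 4), 80, 4,
                dimnames = list(NULL, paste0("n", 1:4)))
    y <- rbinom(80, 1, 0.3)
    if (sum(y) < 2 || sum(1 - y) < 2) next
    cv <- cv_lasso_logistic(X, y, nlambda = 30)
    if (cv$lambda_1se == max(cv$lambda)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("a strong predictor survives lambda_1se while noise is culled", {
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 500
    X <- cbind(true = rnorm(n), matrix(rnorm(n * 5), n, 5,
                                       dimnames = list(NULL,
                                                       paste0("z", 1:5))))
    y <- rbinom(n, 1, plogis(-1 + log(3.8) * X[, "true"]))
    cv <- cv_lasso_logistic(X, y, nlambda = 40)
    b <- coef(cv$fit, s = cv$lambda_1se)[-1L]
    if (b["true"] != 0 && sum(b[paste0("z", 1:5)] == 0) >= 3)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate inputs are rejected", {
  d <- sim_logit(n = 30, seed = 9)
  expect_error(lasso_logistic(d$X, rep(1, 30)), "2 events")
  Xc <- cbind(d$X, flat = 1)
  expect_error(lasso_logistic(Xc, d$y), "constant predictor")
  expect_error(cv_lasso_logistic(d$X[1:8, ], d$y[1:8]), "n >= 10")
})
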
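test_that("intercept-only fit recovers the closed form", {
  y <- c(rep(1, 7), rep(0, 3))
  fit <- fit_logistic(matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")),
                      y)
  p <- 0.7
  expect_equal(unname(coef(fit)), qlogis(p), tolerance = 1e-6)
  expect_equal(fit$log_likelihood,
               10 * (p * log(p) + (1 - p) * log(1 - p)), tolerance = 1e-8)
  expect_false(fit$separation_flag)
})

test_that("the IRLS optimum dominates a coefficient grid", {
  x <- c(-3, -2, -1, 0, 1, 2, 3, 4)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  X <- cbind(1, x)
  fit <- fit_logistic(X, y)
  grid <- expand.grid(b0 = seq(-3, 3, length.out = 41),
                      b1 = seq(-3, 3, length.out = 41))
  ll_grid <- apply(grid, 1, function(b)
    sum(plogis(ifelse(y == 1, 1, -1) * drop(X %*% b), log.p = TRUE)))
  expect_gte(fit$log_likelihood, max(ll_grid))
})

test_that("fit agrees with the reference GLM on regular data", {
  set.seed(14)
  for (i in 1:5) {
    n <- 150
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.3, 0.8, -0.5, 0.2))))
    fit <- fit_logistic(X, y)
    ref <- glm(y ~ X - 1, family = binomial())
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
    expect_equal(fit$log_likelihood, as.numeric(logLik(ref)),
                 tolerance = 1e-7)
    expect_equal(sqrt(diag(fit$vcov)), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-8)  # score eqn
  }
})

test_that("separation is flagged and stabilised by the ridge", {
  x <- c(rep(0, 6), rep(1, 6))
  y <- x
  fit <- fit_logistic(cbind(1, x), y)
  expect_true(fit$separation_flag)
  expect_true(fit$converged)
  expect_true(all(is.finite(coef(fit))))
  expect_gt(fit$log_likelihood, -0.5)  # near-perfect fit, logL near 0
  expect_lte(fit$log_likelihood, 0)
})

test_that("adding columns never lowers the maximised log-likelihood", {
  set.seed(27)
  for (i in 1:15) {
    n <- 80
    X <- cbind(1, matrix(rnorm(n * 4), n))
    y <- rbinom(n, 1, plogis(rnorm(n)))
    lls <- sapply(2:5, function(k)
      fit_logistic(X[, 1:k, drop = FALSE], y)$log_likelihood)
    expect_true(all(diff(lls) >= -1e-6))
  }
})

test_that("the long design has the stated shape and blocks", {
  b <- simulate_battery(sim_config(seed = 16))
  d <- build_long_design(b)
  expect_identical(nrow(d$X), 456L)          # 76 children x 6 tasks
  expect_identical(length(d$assign$task_dummies), 5L)
  expect_false("sex_by_task" %in% names(d$assign))
  d2 <- build_long_design(b, c("age", "gender", "siblings_composite",
                               "task_dummies", "subject_disambiguator",
                               "sex_by_task"))
  expect_identical(length(d2$assign$sex_by_task), 5L)
  expect_error(build_long_design(b, "height"), "unknown factor")
})

test_that("siblings composite spends categories-minus-one columns", {
  covs <- toy_covariates(6)
  covs$n_siblings <- c(0, 1, 1, 0, 1, 0)
  covs$birth_order <- c(1, 1, 2, 1, 2, 1)   # observed pairs (0,1),(1,1),(1,2)
  b <- tom_battery(matrix(rep(c(0L, 1L), 18), 6, 6), covs)
  d <- build_long_design(b, c("age", "siblings_composite"))
  expect_identical(length(d$assign$siblings_composite), 2L)
})

test_that("aliased designs fail loudly with the column named", {
  covs <- toy_covariates(10)
  covs$gender <- 1  # constant girls: gender duplicates the intercept
  b <- tom_battery(matrix(rbinom(60, 1, 0.5), 10, 6), covs)
  expect_error(build_long_design(b, c("age", "gender")),
               "rank deficient.*gender")
})

test_that("factor removal LRT handles the degenerate cases", {
  b <- simulate_battery(sim_config(seed = 19))
  empty <- factor_importance(b, character(0))
  expect_identical(empty$statistic, 0)
  expect_identical(empty$p, 1)
  only <- factor_importance(b, "age", factors = "age")
  d <- build_long_design(b, "age")
  manual <- 2 * (fit_logistic(d$X, d$y)$log_likelihood -
                   fit_logistic(d$X[, 1, drop = FALSE], d$y)$log_likelihood)
  expect_equal(only$statistic, manual, tolerance = 1e-8)
  expect_identical(only$df, 1L)
  expect_error(factor_importance(b, "sex_by_task"), "not part of the model")
})

test_that("sex-task interaction statistic is a nonnegative 5-df LRT", {
  b <- simulate_battery(sim_config(seed = 23))
  t <- sex_task_interaction_test(b)
  expect_gte(t$statistic, 0)
  expect_identical(t$df, 5L)
  expect_true(t$p > 0 && t$p <= 1)
})

test_that("a strong gender effect is recovered by the full model", {
  cfg <- sim_config(n_children = 2000, beta_gender = 0.8, slip = 0,
                    guess = 0, ability_sd = 0, seed = 77)
  fit <- tom_task_model(simulate_battery(cfg))
  expect_lt(abs(coef(fit)[["gender"]] - 0.8), 0.25)
})
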
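test_that("per-task designs carry the right history columns", {
  b <- simulate_battery(sim_config(seed = 41))
  d3c <- build_task_dataset(b, 3, "cumulative")
  expect_identical(sum(grepl("^prev", colnames(d3c$X))), 2L)  # tasks 1, 2
  d4m <- build_task_dataset(b, 4, "markov")
  expect_identical(colnames(d4m$X)[ncol(d4m$X)], "prevKA")
  expect_identical(sum(grepl("^prev", colnames(d4m$X))), 1L)
  # task 2: markov and cumulative coincide; task 1: pointwise = markov
  d2m <- build_task_dataset(b, 2, "markov")
  d2c <- build_task_dataset(b, 2, "cumulative")
  expect_identical(colnames(d2m$X), colnames(d2c$X))
  expect_identical(d2m$X, d2c$X)
  expect_identical(build_task_dataset(b, 1, "markov")$X,
                   build_task_dataset(b, 1, "pointwise")$X)
  expect_error(build_task_dataset(b, 5, "markov"), "1..4")
})

test_that("the nesting chain of log-likelihoods holds on any dataset", {
  seeds <- c(3, 8, 15)
  for (s in seeds) {
    covs <- toy_covariates(60, seed = s)
    set.seed(s)
    resp <- matrix(rbinom(60 * 6, 1, 0.5), 60)  # adversarial: no structure
    b <- tom_battery(resp, covs)
    for (k in 2:4) {
      lls <- sapply(c("pointwise", "markov", "cumulative"), function(kind) {
        d <- build_task_dataset(b, k, kind)
        fit_logistic(d$X, d$y)$log_likelihood
      })
      expect_true(all(diff(lls) >= -1e-6))
    }
  }
})

test_that("comparison table has the Table-1 layout with the dash cell", {
  b <- simulate_battery(sim_config(seed = 47))
  tab <- compare_model_sets(b)
  expect_identical(tab$task, c(2L, 3L, 4L))
  expect_true(is.na(tab$p_markov_vs_cumulative[1]))
  expect_true(all(tab$p_markov_vs_cumulative[2:3] > 0 &
                    tab$p_markov_vs_cumulative[2:3] <= 1))
  expect_true(all(tab$p_pointwise_vs_markov > 0 &
                    tab$p_pointwise_vs_markov <= 1))
  expect_true(all(tab$stat_pointwise_vs_markov >= 0))
  out <- capture.output(print(tab))
  expect_match(out[grep("2 \\(DB\\)", out)], " - ")
})

test_that("perfect scaling makes the previous response decisive at task 2", {
  hits <- sapply(1:10, function(s) {
    b <- simulate_battery(sim_config(n_children = 300, seed = 500 + s),
                          guttman = TRUE)
    tab <- compare_model_sets(b)
    c(reject = tab$p_pointwise_vs_markov[1] < 0.05,
      separation = tab$separation[1])
  })
  expect_gte(mean(hits["reject", ]), 0.9)
  expect_true(any(hits["separation", ]))  # guard engages, reported
})

test_that("with independent tasks the history comparisons are null", {
  ps <- sapply(1:120, function(s) {
    cfg <- sim_config(n_children = 200, beta_age = 0, beta_gender = 0,
                      beta_siblings = 0, ability_sd = 0, seed = 900 + s)
    b <- simulate_battery(cfg)
    tab <- compare_model_sets(b)
    tab$p_markov_vs_cumulative[2]   # task 3, 1 df
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_true(mean(ps <= 0.05) <= 0.11)
})

test_that("a first-order process keeps deeper history at nominal level,
           a direct task-1 link gives it power", {
  gen_chain <- function(n, beta13, seed) {
    covs <- toy_covariates(n, seed = seed)
    set.seed(seed)
    x <- matrix(0L, n, 6)
    x[, 1] <- rbinom(n, 1, 0.75)
    for (k in 2:6) {
      eta <- qlogis(0.55) + 1.2 * x[, k - 1] - 0.8 +
        if (k == 3) beta13 * x[, 1] else 0
      x[, k] <- rbinom(n, 1, plogis(eta))
    }
    tom_battery(x, covs)
  }
  null_p <- sapply(1:60, function(s)
    compare_model_sets(gen_chain(500, 0, 1200 + s))$p_markov_vs_cumulative[2])
  expect_true(mean(null_p <= 0.05) <= 0.12)
  alt_p <- sapply(1:40, function(s)
    compare_model_sets(gen_chain(500, 1.5, 1700 + s))$p_markov_vs_cumulative[2])
  expect_gt(mean(alt_p <= 0.05), 0.5)
})
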
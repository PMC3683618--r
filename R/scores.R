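#' Child-level battery scores
#'
#' The primary score of a child is the count of correct target answers
#' across the tasks (`"uniform"`). Two alternative weightings are provided:
#' `"progressive"` weighs task k's answer by k, and `"one_minus_mean"`
#' weighs it by one minus the observed mean performance of that task, so
#' harder tasks count more.
#'
#' @param battery A [tom_battery] (or binary matrix).
#' @param scheme Scoring scheme.
#' @param tasks Task ordinals to include; default all available. Use `1:4`
#'   to restrict to the scale tasks.
#' @return Numeric vector, one score per child. The uniform score is an
#'   integer in 0..length(tasks).
#' @examples
#' b <- simulate_battery(sim_config(seed = 7))
#' cor(tom_score(b), b$covariates$age_months)
#' @export
tom_score <- function(battery,
                      scheme = c("uniform", "progressive", "one_minus_mean"),
                      tasks = NULL) {
  scheme <- match.arg(scheme)
  x <- if (inherits(battery, "tom_battery")) battery$responses
       else as.matrix(battery)
  if (is.null(tasks)) tasks <- seq_len(ncol(x))
  if (any(tasks > ncol(x))) stop("task ordinal beyond available tasks")
  x <- x[, tasks, drop = FALSE]
  w <- switch(scheme,
              uniform = rep(1, length(tasks)),
              progressive = tasks,
              one_minus_mean = 1 - colMeans(x))
  drop(x %*% w)
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' Permutation test for a correlation
#'
#' Non-parametric two-sided test of association: the dependent variable is
#' shuffled B times, breaking the pairing with the predictor, and the
#' correlation recomputed on each surrogate. The p-value is the
#' add-one-corrected proportion of surrogates whose |r| reaches the
#' observed |r|, `p = (1 + #\{|r_b| >= |r_obs|\}) / (1 + B)`, so it is
#' never exactly 0.
#'
#' @param x Predictor vector (held fixed).
#' @param y Dependent vector (shuffled).
#' @param B Number of shuffles (the study's convention is a thousand).
#' @param seed Integer seed; results are deterministic given it.
#' @return An object of classes `tom_permtest` and `htest` with the
#'   observed `r`, the permutation p-value, `B` and the seed.
#' @examples
#' b <- simulate_battery(sim_config(seed = 3))
#' permutation_cor_test(b$covariates$age_months, tom_score(b), seed = 3)
#' @export
permutation_cor_test <- function(x, y, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  r_obs <- pearson_r(x, y)
  r_null <- with_seed(substream(seed, "permutation_cor"), {
    vapply(seq_len(B), function(b) stats::cor(x, sample(y)), numeric(1))
  })
  # small fudge so exact ties in |r| (discrete data) count as extreme
  p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (1 + B)
  structure(list(statistic = c(r = r_obs), p.value = p,
                 parameter = c(B = B),
                 estimate = c(cor = r_obs),
                 null.values = r_null, seed = seed,
                 alternative = "two.sided",
                 method = "Permutation test for Pearson correlation",
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = c("tom_permtest", "htest"))
}

#' Score-covariate correlation table
#'
#' Runs [permutation_cor_test] of the battery score against each requested
#' covariate.
#'
#' @param battery A [tom_battery] with covariates.
#' @param vars Covariate names; default the six studied correlates.
#' @param scheme Scoring scheme passed to [tom_score].
#' @param B,seed Permutation settings; each covariate gets its own
#'   deterministic substream of `seed`.
#' @return data.frame with columns `variable`, `r`, `p`, `B`.
#' @export
correlate_covariates <- function(battery,
                                 vars = c("age_months", "n_siblings",
                                          "birth_order", "surgency",
                                          "negative_affect",
                                          "effortful_control"),
                                 scheme = "uniform", B = 1000, seed = 1L) {
  stopifnot(inherits(battery, "tom_battery"))
  if (is.null(battery$covariates)) stop("battery has no covariates")
  z <- tom_score(battery, scheme)
  rows <- lapply(vars, function(v) {
    if (!v %in% names(battery$covariates)) stop("unknown covariate: ", v)
    tst <- permutation_cor_test(battery$covariates[[v]], z, B = B,
                                seed = substream(seed, v))
    data.frame(variable = v, r = unname(tst$estimate),
               p = tst$p.value, B = B)
  })
  do.call(rbind, rows)
}
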
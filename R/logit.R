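MODEL_FACTORS <- c("age", "gender", "siblings_composite", "task_dummies",
                   "subject_disambiguator", "sex_by_task")

DEFAULT_FACTORS <- c("age", "gender", "siblings_composite", "task_dummies",
                     "subject_disambiguator")

#' Long-format design for the all-task logistic model
#'
#' Stacks the battery into one outcome row per child x task (6n rows) and
#' builds the design matrix for the requested factors:
#' * `age` — age in months, centered at the sample mean;
#' * `gender` — 0 = boy, 1 = girl;
#' * `siblings_composite` — one categorical factor over the observed
#'   (sibling count, birth order) pairs, reference = most frequent pair,
#'   encoding the two interdependent variables jointly;
#' * `task_dummies` — 5 indicator columns for tasks DB..BE (reference DD);
#' * `subject_disambiguator` — indicators for the within-duplicate-group
#'   index (children whose four demographic values coincide are told apart
#'   by the order in which they took the experiment); a single categorical
#'   column, not a full per-subject intercept, which would absorb every
#'   covariate;
#' * `sex_by_task` — gender x task interaction columns (5).
#'
#' Temperament (CBQ) scores are deliberately not part of the model.
#'
#' @param battery A six-task [tom_battery] with covariates.
#' @param factors Character subset of the factor names above.
#' @return List with the design matrix `X` (intercept included), outcome
#'   vector `y`, and `assign`, a named list mapping each factor to its
#'   column indices in `X`.
#' @export
build_long_design <- function(battery, factors = DEFAULT_FACTORS) {
  stopifnot(inherits(battery, "tom_battery"))
  if (is.null(battery$covariates)) stop("battery has no covariates")
  if (length(battery$tasks) != 6L) stop("the long model needs all six tasks")
  bad <- setdiff(factors, MODEL_FACTORS)
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  covs <- battery$covariates
  n <- nrow(covs)
  child <- rep(seq_len(n), times = 6)
  task <- rep(seq_len(6), each = n)
  y <- as.vector(battery$responses)

  task_dum <- sapply(2:6, function(k) as.integer(task == k))
  colnames(task_dum) <- paste0("task", TOM_TASKS[2:6])

  blocks <- list("(Intercept)" = matrix(1, 6 * n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  assign <- list()
  for (f in factors) {
    block <- switch(f,
      age = {
        m <- matrix(rep(covs$age_months - mean(covs$age_months), 6), ncol = 1)
        colnames(m) <- "age_c"; m
      },
      gender = {
        m <- matrix(rep(covs$gender, 6), ncol = 1)
        colnames(m) <- "gender"; m
      },
      siblings_composite = siblings_dummies(covs)[child, , drop = FALSE],
      task_dummies = task_dum,
      subject_disambiguator = disamb_dummies(covs)[child, , drop = FALSE],
      sex_by_task = {
        m <- task_dum * rep(covs$gender, 6)
        colnames(m) <- paste0("gender:", colnames(task_dum)); m
      })
    blocks[[f]] <- block
  }
  X <- do.call(cbind, blocks)
  pos <- 1L
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]])
    if (nm != "(Intercept)") assign[[nm]] <- seq.int(pos, pos + k - 1L)
    pos <- pos + k
  }
  check_full_rank(X)
  list(X = X, y = y, assign = assign, child = child, task = task)
}

siblings_dummies <- function(covs) {
  pair <- paste0("(", covs$n_siblings, ",", covs$birth_order, ")")
  ref <- names(sort(table(pair), decreasing = TRUE))[1]
  lev <- setdiff(sort(unique(pair)), ref)
  m <- sapply(lev, function(l) as.integer(pair == l))
  if (length(lev) == 0) return(matrix(0L, nrow(covs), 0))
  m <- matrix(m, nrow = nrow(covs))
  colnames(m) <- paste0("sib", lev)
  m
}

disamb_dummies <- function(covs) {
  idx <- covs$disambiguation_index
  lev <- setdiff(sort(unique(idx)), 1L)
  if (length(lev) == 0) return(matrix(0L, nrow(covs), 0))
  m <- matrix(sapply(lev, function(l) as.integer(idx == l)), nrow = nrow(covs))
  colnames(m) <- paste0("dup", lev)
  m
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

# Bernoulli log-likelihood, numerically stable via plogis on the log scale.
logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
}

#' Maximum-likelihood logistic fit (IRLS with separation guard)
#'
#' Newton/IRLS maximisation of the Bernoulli log-likelihood with
#' step-halving. Convergence is declared when the log-likelihood changes
#' by less than 1e-8, with a cap of 100 iterations. Complete or
#' quasi-complete separation (a predictor perfectly splitting the
#' outcomes) drives ML coefficients to infinity; it is detected when any
#' coefficient exceeds 15 in absolute value while the likelihood is still
#' climbing, upon which a ridge of 1e-8 is added to the normal equations,
#' the `separation_flag` is set, and the (essentially unpenalised)
#' likelihood is reported at the stabilised coefficients.
#'
#' @param X Numeric design matrix, intercept included, full rank.
#' @param y Binary outcome vector.
#' @param keep_data Store `X` and `y` in the result (needed by `predict`).
#' @return Object of class `tom_logit`: `coefficients`,
#'   `log_likelihood`, `converged`, `n_iterations`, `separation_flag`,
#'   `fitted`, `vcov` (observed-information covariance; NA under
#'   separation), `nobs`, `df`.
#' @export
fit_logistic <- function(X, y, keep_data = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  p <- ncol(X)
  beta <- rep(0, p)
  ridge <- 0
  sep_flag <- FALSE
  obj <- function(b) logistic_loglik(X, y, b) - 0.5 * ridge * sum(b^2)
  ll_old <- obj(beta)
  it <- 0L
  converged <- FALSE
  trace <- numeric(0)
  while (it < 100L) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w)
    if (ridge > 0) H <- H + diag(ridge, p)
    g <- drop(crossprod(X, y - mu)) - ridge * beta
    delta <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, p), g))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- obj(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; ll_new <- ll_old; break }
    }
    beta <- cand
    trace <- c(trace, ll_new)
    moving <- abs(ll_new - ll_old) >= 1e-8
    if (!sep_flag && moving && any(abs(beta) > 15)) {
      sep_flag <- TRUE
      ridge <- 1e-8
      ll_old <- obj(beta)   # objective changed; re-baseline
      next
    }
    if (!moving) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  if (!converged && !sep_flag)
    stop("logistic fit failed to converge in 100 iterations without ",
         "separation; log-likelihood trace tail: ",
         paste(sprintf("%.8f", utils::tail(trace, 5)), collapse = ", "))
  eta <- drop(X %*% beta)
  ll <- sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
  vc <- if (sep_flag) matrix(NA_real_, p, p) else {
    mu <- stats::plogis(eta)
    solve(crossprod(X, X * pmax(mu * (1 - mu), 1e-10)))
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, log_likelihood = ll,
                 converged = converged || sep_flag,
                 n_iterations = it, separation_flag = sep_flag,
                 fitted = stats::plogis(eta), vcov = vc,
                 nobs = length(y), df = p,
                 X = if (keep_data) X, y = if (keep_data) y),
            class = "tom_logit")
}

#' Fit the all-task covariate logistic model
#'
#' User-level wrapper: builds the long design over all six tasks (see
#' [build_long_design]) and fits it by maximum likelihood.
#'
#' @inheritParams build_long_design
#' @return A `tom_logit` with the design's `assign` attached.
#' @examples
#' b <- simulate_battery(sim_config(seed = 5))
#' fit <- tom_task_model(b)
#' coef(fit)[c("age_c", "gender")]
#' @export
tom_task_model <- function(battery, factors = DEFAULT_FACTORS) {
  d <- build_long_design(battery, factors)
  fit <- fit_logistic(d$X, d$y)
  fit$assign <- d$assign
  fit$factors <- factors
  fit
}

#' @export
print.tom_logit <- function(x, ...) {
  cat("Logistic model:", x$nobs, "outcomes,", x$df, "coefficients\n")
  cat(sprintf("logL = %.4f (%s in %d iterations%s)\n", x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (x$separation_flag) "; separation detected, ridge applied"
              else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.tom_logit <- function(object, ...) object$coefficients

#' @export
logLik.tom_logit <- function(object, ...) {
  structure(object$log_likelihood, df = object$df,
            nobs = object$nobs, class = "logLik")
}

#' @export
vcov.tom_logit <- function(object, ...) object$vcov

#' @export
summary.tom_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab,
                 log_likelihood = object$log_likelihood,
                 separation_flag = object$separation_flag),
            class = "summary.tom_logit")
}

#' @export
print.summary.tom_logit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("logL = %.4f\n", x$log_likelihood))
  if (x$separation_flag)
    cat("Warning: separation detected; Wald quantities unreliable, ",
        "use likelihood-ratio tests.\n")
  invisible(x)
}

#' @export
predict.tom_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  if (is.null(X)) stop("fit was stored without data; supply newdata")
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.tom_logit <- function(object, type = c("deviance", "response"),
                                ...) {
  type <- match.arg(type)
  if (is.null(object$y)) stop("fit was stored without data")
  r <- object$y - object$fitted
  if (type == "response") return(r)
  eta <- drop(object$X %*% object$coefficients)
  lli <- stats::plogis(ifelse(object$y == 1, eta, -eta), log.p = TRUE)
  sign(r) * sqrt(-2 * lli)
}

# Likelihood-ratio test of nested fits; tiny negative statistics (numerical
# noise near ridge-stabilised optima) are clamped to 0, larger ones error.
lr_test <- function(fit_full, fit_reduced, df) {
  stat <- 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood)
  if (stat < 0) {
    if (stat > -1e-6) stat <- 0
    else stop("negative LRT statistic (", stat, "): models not nested?")
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 separation = fit_full$separation_flag ||
                   fit_reduced$separation_flag),
            class = "tom_lrt")
}

#' @export
print.tom_lrt <- function(x, ...) {
  cat(sprintf("LRT: 2*dlogL = %.4f on %d df, p = %.4g%s\n", x$statistic,
              x$df, x$p,
              if (x$separation) " [separation guard engaged]" else ""))
  invisible(x)
}

#' Factor-removal likelihood-ratio importance test
#'
#' Measures the importance of one factor in the all-task logistic model by
#' comparing the full model to the model with that factor removed: twice
#' the log-likelihood difference is referred to a chi-square distribution
#' with as many degrees of freedom as columns removed.
#'
#' @inheritParams build_long_design
#' @param factor One of the names in `factors`, or `character(0)` for the
#'   degenerate empty removal (statistic 0, p = 1). Removing the only
#'   factor compares against the intercept-only model.
#' @return A `tom_lrt`: `statistic`, `df`, `p`, plus the removed factor
#'   name.
#' @examples
#' b <- simulate_battery(sim_config(seed = 11))
#' factor_importance(b, "gender")
#' @export
factor_importance <- function(battery, factor,
                              factors = DEFAULT_FACTORS) {
  full <- tom_task_model(battery, factors)
  if (length(factor) == 0) {
    out <- lr_test(full, full, 0L)
    out$factor <- character(0)
    return(out)
  }
  if (!factor %in% factors)
    stop("factor ", factor, " is not part of the model")
  reduced_factors <- setdiff(factors, factor)
  reduced <- if (length(reduced_factors)) {
    tom_task_model(battery, reduced_factors)
  } else {
    d <- build_long_design(battery, factors)
    fit_logistic(d$X[, 1, drop = FALSE], d$y)
  }
  out <- lr_test(full, reduced, full$df - reduced$df)
  out$factor <- factor
  out
}

#' Sex-by-task interaction test
#'
#' Tests whether the gender effect is task-dependent: the default model
#' expanded with a joint sex x task factor (5 extra columns) is compared
#' with the default model by likelihood ratio on 5 df. Non-rejection says
#' the girl advantage is shared across tasks.
#'
#' @inheritParams build_long_design
#' @return A `tom_lrt`.
#' @export
sex_task_interaction_test <- function(battery,
                                      factors = DEFAULT_FACTORS) {
  full <- tom_task_model(battery, c(factors, "sex_by_task"))
  reduced <- tom_task_model(battery, factors)
  out <- lr_test(full, reduced, full$df - reduced$df)
  out$factor <- "sex_by_task"
  out
}
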
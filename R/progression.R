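#' Per-task dataset for the model-set comparison
#'
#' One row per child; the outcome is the response to scale task k and the
#' predictors depend on the model-set kind:
#' * `"pointwise"` — age (centered), gender and the joint (sibling count,
#'   birth order) categorical only;
#' * `"markov"` — pointwise plus the response to task k-1;
#' * `"cumulative"` — pointwise plus the whole history of responses to
#'   tasks 1..k-1.
#'
#' For task 1 pointwise and markov coincide; for task 2 markov and
#' cumulative coincide. The subject disambiguator is omitted: with one row
#' per child there are no repeated measures to disambiguate.
#'
#' @param battery A [tom_battery] with covariates, covering tasks 1..k.
#' @param k Scale-task ordinal in 1..4.
#' @param kind One of `"pointwise"`, `"markov"`, `"cumulative"`.
#' @return List with design matrix `X` (intercept included) and outcome
#'   `y`.
#' @export
build_task_dataset <- function(battery, k,
                               kind = c("pointwise", "markov",
                                        "cumulative")) {
  kind <- match.arg(kind)
  stopifnot(inherits(battery, "tom_battery"))
  if (is.null(battery$covariates)) stop("battery has no covariates")
  if (!k %in% 1:4) stop("k must be a scale-task ordinal in 1..4")
  covs <- battery$covariates
  x <- battery$responses
  X <- cbind("(Intercept)" = 1,
             age_c = covs$age_months - mean(covs$age_months),
             gender = covs$gender,
             siblings_dummies(covs))
  hist_cols <- switch(kind,
                      pointwise = integer(0),
                      markov = if (k >= 2) k - 1L else integer(0),
                      cumulative = seq_len(k - 1L))
  dropped <- character(0)
  if (length(hist_cols)) {
    h <- x[, hist_cols, drop = FALSE]
    colnames(h) <- paste0("prev", TOM_TASKS[hist_cols])
    # a constant history column (every child passing, or failing, an
    # earlier task) carries no information and is aliased with the
    # intercept; drop it rather than fail, and record the fact
    const <- apply(h, 2, function(v) length(unique(v)) == 1L)
    dropped <- colnames(h)[const]
    X <- cbind(X, h[, !const, drop = FALSE])
  }
  check_full_rank(X)
  list(X = X, y = as.numeric(x[, k]), k = k, kind = kind,
       dropped_history = dropped)
}

#' Pointwise / Markov / Cumulative model-set comparison
#'
#' For each scale task k = 2..4, fits the three nested per-task logistic
#' models and tests, by likelihood ratio, whether the extra history
#' variables are explanatory: Pointwise vs Markov asks if the previous
#' task's response predicts the current one beyond the covariates (1 df);
#' Markov vs Cumulative asks if history beyond the previous task adds
#' anything (k-2 df, defined for k >= 3). In a well-scaled battery the
#' previous response is informative but deeper history is not.
#'
#' Near-separation is expected on strongly scaled data (failing task k-1
#' almost implies failing task k); the ridge guard of [fit_logistic]
#' engages and is reported per cell, never silently ignored.
#'
#' @param battery A [tom_battery] with covariates covering tasks 1-4.
#' @return Object of class `tom_progression`: a data.frame with one row
#'   per task k = 2..4 and columns `task`, `code`,
#'   `p_markov_vs_cumulative` (NA for k = 2, printed as the dash
#'   sentinel), `p_pointwise_vs_markov`, plus separation flags.
#' @examples
#' b <- simulate_battery(sim_config(seed = 2))
#' compare_model_sets(b)
#' @export
compare_model_sets <- function(battery) {
  n <- nrow(battery$responses)
  rows <- lapply(2:4, function(k) {
    dp <- build_task_dataset(battery, k, "pointwise")
    dm <- build_task_dataset(battery, k, "markov")
    if (n < ncol(dm$X) + 5 + (k - 2))
      stop("too few children (", n, ") for the task-", k, " comparison")
    fp <- fit_logistic(dp$X, dp$y, keep_data = FALSE)
    fm <- fit_logistic(dm$X, dm$y, keep_data = FALSE)
    pm <- lr_test(fm, fp, fm$df - fp$df)
    if (k >= 3) {
      dc <- build_task_dataset(battery, k, "cumulative")
      fc <- fit_logistic(dc$X, dc$y, keep_data = FALSE)
      mc <- lr_test(fc, fm, fc$df - fm$df)
    } else mc <- NULL
    data.frame(task = k, code = TOM_SCALE_TASKS[k],
               p_markov_vs_cumulative = if (is.null(mc)) NA_real_ else mc$p,
               p_pointwise_vs_markov = pm$p,
               stat_markov_vs_cumulative = if (is.null(mc)) NA_real_
                                           else mc$statistic,
               stat_pointwise_vs_markov = pm$statistic,
               separation = pm$separation ||
                 (!is.null(mc) && mc$separation))
  })
  structure(do.call(rbind, rows), class = c("tom_progression",
                                            "data.frame"))
}

#' @export
print.tom_progression <- function(x, digits = 3, ...) {
  cat("Model sets comparison (per scale task)\n")
  cat(sprintf("%-8s %-24s %-24s\n", "Task", "p Markov vs. Cumulative",
              "p Pointwise vs. Markov"))
  for (i in seq_len(nrow(x))) {
    mc <- if (is.na(x$p_markov_vs_cumulative[i])) "-"
          else format(round(x$p_markov_vs_cumulative[i], digits))
    cat(sprintf("%-8s %-24s %-24s%s\n",
                paste0(x$task[i], " (", x$code[i], ")"), mc,
                format(round(x$p_pointwise_vs_markov[i], digits)),
                if (x$separation[i]) "  [separation guard]" else ""))
  }
  invisible(x)
}
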
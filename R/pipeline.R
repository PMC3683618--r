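#' Pipeline run configuration
#'
#' Describes a full analysis run: where the battery comes from (a CSV
#' battery table, the built-in fixture, or the synthetic generator), which
#' analyses to perform, and the stochastic settings. A seed is mandatory:
#' every stochastic stage draws from its own deterministic substream of
#' it, so adding or removing a stage never perturbs the others.
#'
#' @param input Path to a battery table CSV, the string `"fixture"` for
#'   the built-in aggregate-matched matrix, or a [tom_battery] object.
#'   Ignored when `simulate` is given.
#' @param simulate Optional [sim_config]; when given, the battery is
#'   generated (the generator's own seed is replaced by the run's
#'   `"simulate"` substream so one top-level seed governs the run).
#' @param analyses Subset of `c("scaling", "correlations", "glm",
#'   "progression")`; the aggregate summary is always produced.
#' @param B Permutation/shuffle count for the stochastic analyses.
#' @param scheme Shuffle scheme for the scaling test.
#' @param seed Integer top-level seed.
#' @return List of class `tom_run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       analyses = c("scaling", "correlations", "glm",
                                    "progression"),
                       B = 1000, scheme = "global", seed = 1L) {
  bad <- setdiff(analyses, c("scaling", "correlations", "glm",
                             "progression"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (is.null(input) && is.null(simulate))
    stop("either input or simulate must be given")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "tom_sim_config"))
  if (length(analyses) && is.null(seed)) stop("seed is mandatory")
  structure(list(input = input, simulate = simulate, analyses = analyses,
                 B = as.integer(B), scheme = scheme,
                 seed = as.integer(seed)),
            class = "tom_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in fixed order — data, aggregate summary,
#' scaling, correlations, covariate logistic model, model progression —
#' and collects everything in a plain, serialisable report. Identical
#' configuration and seed produce identical reports.
#'
#' @param config A [run_config].
#' @return Object of class `tom_report`: nested lists and data.frames
#'   (see [render_report] for the on-disk form), with a provenance block
#'   recording config echo, seed, B and package version.
#' @examples
#' rep <- run_pipeline(run_config(input = "fixture",
#'                                analyses = "scaling", B = 200, seed = 9))
#' rep$scaling$figure_of_merit  # 27
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tom_run_config"))
  battery <- pipeline_battery(config)
  report <- list(
    provenance = list(
      package = "tomscale",
      version = as.character(utils::packageVersion("tomscale")),
      seed = config$seed, B = config$B, scheme = config$scheme,
      analyses = as.character(config$analyses),
      input = input_echo(config)))
  s <- tryCatch(battery_summary(battery), error = function(e)
    stop("stage summary failed: ", conditionMessage(e)))
  report$summary <- list(n_children = s$n_children,
                         pass_counts = unname(s$pass_counts),
                         violations = unname(s$violations))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e)))
  }
  if ("scaling" %in% config$analyses) {
    sc <- run_stage("scaling",
      scaling_test(battery, scheme = config$scheme, B = config$B,
                   seed = substream(config$seed, "scaling")))
    report$scaling <- list(
      violations = unname(sc$violations),
      figure_of_merit = sc$figure_of_merit, p = sc$p,
      scheme = sc$scheme, B = sc$B, seed = sc$seed,
      null_mean = mean(sc$null_values), null_sd = stats::sd(sc$null_values),
      diagram = inclusion_diagram(battery))
  }
  if ("correlations" %in% config$analyses) {
    report$correlations <- run_stage("correlations",
      correlate_covariates(battery, B = config$B,
                           seed = substream(config$seed, "correlations")))
  }
  if ("glm" %in% config$analyses) {
    report$glm <- run_stage("glm", glm_stage(battery))
  }
  if ("progression" %in% config$analyses) {
    prog <- run_stage("progression", compare_model_sets(battery))
    report$progression <- as.data.frame(prog)
  }
  structure(report, class = "tom_report")
}

pipeline_battery <- function(config) {
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- substream(config$seed, "simulate")
    return(simulate_battery(cfg))
  }
  if (inherits(config$input, "tom_battery")) return(config$input)
  if (identical(config$input, "fixture")) return(fixture_battery())
  read_battery_table(config$input)
}

input_echo <- function(config) {
  if (!is.null(config$simulate))
    return(list(kind = "simulate", config = unclass(config$simulate)))
  if (inherits(config$input, "tom_battery"))
    return(list(kind = "battery_object"))
  list(kind = "file", path = unname(config$input))
}

glm_stage <- function(battery) {
  fit <- tom_task_model(battery)
  lrt_rows <- lapply(c("age", "gender", "siblings_composite"), function(f) {
    t <- factor_importance(battery, f)
    data.frame(factor = f, df = t$df, statistic = t$statistic, p = t$p,
               separation = t$separation)
  })
  it <- sex_task_interaction_test(battery)
  lrt_rows <- c(lrt_rows, list(
    data.frame(factor = "sex_by_task", df = it$df, statistic = it$statistic,
               p = it$p, separation = it$separation)))
  list(coefficients = data.frame(term = names(fit$coefficients),
                                 estimate = unname(fit$coefficients)),
       log_likelihood = fit$log_likelihood,
       converged = fit$converged,
       separation_flag = fit$separation_flag,
       lrt = do.call(rbind, lrt_rows))
}

#' @export
print.tom_report <- function(x, ...) {
  cat("== tomscale report (seed ", x$provenance$seed, ", B ",
      x$provenance$B, ") ==\n", sep = "")
  cat("Input:", x$provenance$input$kind, "\n")
  cat("Children:", x$summary$n_children, "; pass counts ",
      paste(x$summary$pass_counts, collapse = ", "),
      "; violations ", paste(x$summary$violations, collapse = ", "), "\n")
  if (!is.null(x$scaling))
    cat(sprintf("Scaling: M = %d, shuffle-null p = %.4g (%s)\n",
                x$scaling$figure_of_merit, x$scaling$p, x$scaling$scheme))
  if (!is.null(x$correlations)) {
    cat("Score-covariate permutation tests:\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$glm)) {
    cat(sprintf("Covariate logistic model: logL = %.3f%s\n",
                x$glm$log_likelihood,
                if (x$glm$separation_flag) " [separation]" else ""))
    print(x$glm$lrt, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$progression))

    print(structure(x$progression, class = c("tom_progression",
                                             "data.frame")))
  invisible(x)
}

#' Render and parse a pipeline report
#'
#' `render_report` writes the machine-readable form (JSON, full numeric
#' precision) and a human-readable text rendering; the inclusion-diagram
#' data, when present, is also written as CSV for plotting.
#' `parse_report` reads the JSON back into an identical `tom_report`.
#'
#' @param report A `tom_report`.
#' @param dir Output directory (created if needed).
#' @return `render_report`: named vector of written paths, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "tom_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "w", encoding = "UTF-8")
  sink(con); print(report); sink()
  close(con)
  paths <- c(json = json_path, text = txt_path)
  if (!is.null(report$scaling)) {
    diag_path <- file.path(dir, "inclusion_diagram.csv")
    utils::write.csv(report$scaling$diagram, diag_path, row.names = FALSE)
    paths <- c(paths, diagram = diag_path)
  }
  invisible(paths)
}

#' @rdname render_report
#' @param path Path to a `report.json` written by `render_report`.
#' @export
parse_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(rep, class = "tom_report")
}
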
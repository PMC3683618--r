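#' Ordered task codes of the battery
#'
#' The six tasks, in their fixed scale order: Diverse Desires (DD), Diverse
#' Beliefs (DB), Knowledge Access (KA), Contents False Belief (FB), Explicit
#' False Belief (EFB) and Belief vs. Emotion (BE). Only the first four take
#' part in the scaling analyses.
#'
#' @format Character vector of length 6.
#' @export
TOM_TASKS <- c("DD", "DB", "KA", "FB", "EFB", "BE")

#' @rdname TOM_TASKS
#' @export
TOM_SCALE_TASKS <- TOM_TASKS[1:4]

COVARIATE_COLS <- c("age_months", "gender", "n_siblings", "birth_order",
                    "surgency", "negative_affect", "effortful_control")

#' Construct a battery object
#'
#' Bundles a children x tasks binary response matrix (1 = target question
#' answered correctly) with optional per-child covariates into a validated
#' container. Control questions are not stored: every child in the study
#' design answers them correctly, so they carry no information.
#'
#' @param responses Binary matrix, one row per child. Columns must be the
#'   first `ncol(responses)` tasks of [TOM_TASKS] in order (either the four
#'   scale tasks or all six); unnamed columns are assumed to be in task order
#'   and are named.
#' @param covariates Optional data.frame with columns `age_months`, `gender`
#'   (0 = boy, 1 = girl), `n_siblings`, `birth_order`, `surgency`,
#'   `negative_affect`, `effortful_control`. A `disambiguation_index` column
#'   is (re)computed: children sharing the same (age, gender, siblings,
#'   birth order) tuple are numbered 1, 2, ... in row order; unique children
#'   get 1.
#' @return An object of class `tom_battery`: a list with elements
#'   `responses`, `covariates` (or NULL) and `tasks`.
#' @examples
#' m <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' b <- tom_battery(m)
#' battery_summary(b)
#' @export
tom_battery <- function(responses, covariates = NULL) {
  responses <- as.matrix(responses)
  if (!ncol(responses) %in% c(4L, 6L))
    stop("responses must have 4 (scale tasks) or 6 columns, got ",
         ncol(responses))
  tasks <- TOM_TASKS[seq_len(ncol(responses))]
  if (is.null(colnames(responses))) {
    colnames(responses) <- tasks
  } else if (!identical(colnames(responses), tasks)) {
    stop("response columns must be ", paste(tasks, collapse = ", "),
         " in scale order")
  }
  bad <- which(!(responses %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(responses))
    stop("non-binary response at row ", i[1], ", column ",
         colnames(responses)[i[2]], ": ", responses[bad[1]])
  }
  storage.mode(responses) <- "integer"
  rownames(responses) <- NULL
  if (!is.null(covariates)) {
    covariates <- validate_covariates(covariates, nrow(responses))
  }
  structure(list(responses = responses, covariates = covariates,
                 tasks = tasks),
            class = "tom_battery")
}

validate_covariates <- function(covs, n_children) {
  covs <- as.data.frame(covs)
  missing_cols <- setdiff(COVARIATE_COLS, names(covs))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(covs) != n_children)
    stop("covariates have ", nrow(covs), " rows but the matrix has ",
         n_children, " children")
  if (any(covs$age_months <= 0))
    stop("non-positive age_months at row ", which(covs$age_months <= 0)[1])
  if (!all(covs$gender %in% c(0, 1)))
    stop("gender must be coded 0 (boy) / 1 (girl); bad value at row ",
         which(!covs$gender %in% c(0, 1))[1])
  bad_bo <- which(covs$birth_order > covs$n_siblings + 1 | covs$birth_order < 1)
  if (length(bad_bo))
    stop("birth_order out of range 1..n_siblings+1 at row ", bad_bo[1],
         ", column birth_order")
  covs <- covs[c(COVARIATE_COLS)]
  covs$disambiguation_index <- disambiguation_index(covs)
  rownames(covs) <- NULL
  covs
}

# 1, 2, ... in first-occurrence order within each group of children whose
# (age, gender, siblings, birth order) coincide; 1 for unique children.
disambiguation_index <- function(covs) {
  key <- paste(covs$age_months, covs$gender, covs$n_siblings,
               covs$birth_order, sep = "\r")
  idx <- integer(length(key))
  for (k in unique(key)) {
    rows <- which(key == k)
    idx[rows] <- seq_along(rows)
  }
  idx
}

#' @export
print.tom_battery <- function(x, ...) {
  cat("Task battery:", nrow(x$responses), "children x",
      length(x$tasks), "tasks (", paste(x$tasks, collapse = " < "), ")\n")
  cat("Per-task pass counts:",
      paste(colSums(x$responses), collapse = ", "), "\n")
  if (is.null(x$covariates)) {
    cat("No covariates attached.\n")
  } else {
    cat("Covariates: age", paste(range(x$covariates$age_months),
                                 collapse = "-"), "months;",
        sum(x$covariates$gender == 1), "girls,",
        sum(x$covariates$gender == 0), "boys\n")
  }
  invisible(x)
}

#' Read a battery table from delimited text
#'
#' Reads a headered comma-delimited file with one row per child: the seven
#' covariate columns followed by the six task outcome columns (see
#' [write_battery_table] for the exact layout). Validates every cell and
#' assigns disambiguation indices.
#'
#' @param path Path to a CSV file.
#' @return A [tom_battery] with covariates.
#' @export
read_battery_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  needed <- c(COVARIATE_COLS, TOM_TASKS)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  resp <- as.matrix(tab[TOM_TASKS])
  tom_battery(resp, tab[COVARIATE_COLS])
}

#' Write a battery table as delimited text
#'
#' Inverse of [read_battery_table]: columns `age_months, gender, n_siblings,
#' birth_order, surgency, negative_affect, effortful_control, DD, DB, KA,
#' FB, EFB, BE`, comma-delimited, UTF-8. Round-trips exactly.
#'
#' @param battery A six-task [tom_battery] with covariates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battery_table <- function(battery, path) {
  stopifnot(inherits(battery, "tom_battery"))
  if (is.null(battery$covariates))
    stop("battery has no covariates; a battery table needs them")
  if (length(battery$tasks) != 6L)
    stop("battery table format requires all six tasks")
  tab <- cbind(battery$covariates[COVARIATE_COLS],
               as.data.frame(battery$responses))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate pass and violation counts
#'
#' Per-task pass counts for the four scale tasks and the successive
#' violation counts |G_(k+1) \ G_k|, i.e. the number of children passing
#' task k+1 while failing task k, for k = 1..3.
#'
#' @param battery A [tom_battery] (or binary matrix) covering at least the
#'   four scale tasks.
#' @return Object of class `tom_summary`: list with `n_children`,
#'   `pass_counts` (named, tasks 1-4) and `violations` (named by task pair).
#' @examples
#' battery_summary(fixture_battery())
#' @export
battery_summary <- function(battery) {
  x <- scale_matrix(battery)
  K <- ncol(x)
  pass <- colSums(x)
  viol <- vapply(seq_len(K - 1), function(k)
    sum(x[, k + 1] == 1 & x[, k] == 0), integer(1))
  names(viol) <- paste(colnames(x)[-1], colnames(x)[-K], sep = ">")
  structure(list(n_children = nrow(x), pass_counts = pass,
                 violations = viol),
            class = "tom_summary")
}

# Extract the scale-task submatrix from a battery or matrix: the first
# four columns of a full battery (scaling never uses EFB/BE), or a short
# ordered battery of 2-4 tasks as-is (used by small exact-test examples).
scale_matrix <- function(battery) {
  x <- if (inherits(battery, "tom_battery")) battery$responses
       else as.matrix(battery)
  if (ncol(x) < 2L)
    stop("scaling analyses need at least two ordered tasks")
  x <- x[, seq_len(min(ncol(x), 4L)), drop = FALSE]
  colnames(x) <- TOM_SCALE_TASKS[seq_len(ncol(x))]
  storage.mode(x) <- "integer"
  x
}

#' @export
print.tom_summary <- function(x, ...) {
  cat("Children:", x$n_children, "\n")
  cat("Pass counts:",
      paste(sprintf("%s=%d", names(x$pass_counts), x$pass_counts),
            collapse = ", "), "\n")
  cat("Successive violations:",
      paste(sprintf("%s: %d", names(x$violations), x$violations),
            collapse = ", "), "\n")
  cat("Figure of merit M =", sum(x$violations), "\n")
  invisible(x)
}

#' Deterministic fixture matrix matching the published aggregates
#'
#' Reconstructs a 76 x 4 binary matrix whose aggregate summary equals the
#' published cohort exactly: 62/56/48/36 children passing DD/DB/KA/FB and
#' successive violation counts 6, 11, 10 (figure of merit 27). Individual
#' rows are not published; the construction is the simplest deterministic
#' arrangement compatible with every printed aggregate. Children are
#' indexed 1-76: DD passes 1-62; DB passes 1-50 plus 63-68; KA passes 1-37
#' plus 51-61; FB passes 1-26 plus 38-47. Non-successive overlaps are not
#' constrained by the printed aggregates and must not be treated as data.
#'
#' @return A [tom_battery] with four tasks and no covariates.
#' @examples
#' figure_of_merit(fixture_battery())  # 27
#' @export
fixture_battery <- function() {
  m <- matrix(0L, 76, 4, dimnames = list(NULL, TOM_SCALE_TASKS))
  m[1:62, 1] <- 1L
  m[c(1:50, 63:68), 2] <- 1L
  m[c(1:37, 51:61), 3] <- 1L
  m[c(1:26, 38:47), 4] <- 1L
  tom_battery(m)
}
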
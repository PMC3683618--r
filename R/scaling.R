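#' Pass sets of the scale tasks
#'
#' G_k is the set of children answering task k's target question correctly,
#' for the four scale tasks. A perfect developmental hierarchy has
#' G_4 in G_3 in G_2 in G_1.
#'
#' @param battery A [tom_battery] or binary matrix covering tasks 1-4.
#' @return Named list of integer index vectors `G1`..`G4`.
#' @export
pass_sets <- function(battery) {
  x <- scale_matrix(battery)
  sets <- lapply(seq_len(ncol(x)), function(k) which(x[, k] == 1L))
  names(sets) <- paste0("G", seq_len(ncol(x)))
  sets
}

#' Figure of merit of the scaling
#'
#' The total number of successive-inclusion violations
#' `M = sum_k |G_(k+1) \ G_k|`: cases in which a child passed a task
#' without passing the previous one. M = 0 iff the inclusion chain holds
#' exactly; lower values represent better scalings.
#'
#' @param battery A [tom_battery], binary matrix, or the result of
#'   [pass_sets].
#' @return Integer count.
#' @examples
#' figure_of_merit(fixture_battery())  # 27
#' @export
figure_of_merit <- function(battery) {
  if (is.list(battery) && !inherits(battery, "tom_battery") &&
      all(paste0("G", seq_along(battery)) %in% names(battery))) {
    return(sum(vapply(seq_len(length(battery) - 1), function(k)
      length(setdiff(battery[[k + 1]], battery[[k]])), integer(1))))
  }
  x <- scale_matrix(battery)
  fom_matrix(x)
}

# Hot path shared with the shuffle null.
fom_matrix <- function(x) {
  K <- ncol(x)
  sum(x[, -1, drop = FALSE] == 1L & x[, -K, drop = FALSE] == 0L)
}

# One surrogate matrix under a shuffle scheme. global: all 4n cells
# permuted jointly; within_child: each row's entries permuted; within_task:
# each column's entries permuted.
shuffle_matrix <- function(x, scheme) {
  n <- nrow(x)
  switch(scheme,
         global = matrix(x[sample.int(length(x))], n),
         within_child = t(vapply(seq_len(n),
                                 function(i) x[i, sample.int(ncol(x))],
                                 integer(ncol(x)))),
         within_task = vapply(seq_len(ncol(x)),
                              function(k) x[sample.int(n), k],
                              integer(n)),
         stop("unknown shuffle scheme: ", scheme))
}

#' Shuffle-null significance of the figure of merit
#'
#' Tests whether the observed figure of merit M is smaller than expected
#' under a null in which the cell values of the response matrix are
#' permuted. Three schemes are provided because "shuffling kids and tasks"
#' admits several readings and the null is scheme-dependent:
#' `"global"` (default) permutes all cells jointly, destroying both row and
#' column structure; `"within_child"` permutes each child's four answers,
#' preserving individual scores but destroying task order; `"within_task"`
#' permutes each column, preserving task difficulty but destroying child
#' identity. Every scheme conserves the grand total of passes.
#'
#' The test is one-sided with small M extreme (low M = good scaling):
#' `p = (1 + #\{M_b <= M_obs\}) / (1 + B)`.
#'
#' @param battery A [tom_battery] or binary matrix covering tasks 1-4.
#' @param scheme Shuffle scheme.
#' @param B Number of surrogates.
#' @param seed Integer seed.
#' @return Object of class `tom_scaling`: observed violations, `M`, the B
#'   surrogate values, `p`, scheme and seed.
#' @examples
#' scaling_test(fixture_battery(), B = 200, seed = 42)
#' @export
scaling_test <- function(battery,
                         scheme = c("global", "within_child", "within_task"),
                         B = 1000, seed = 1L) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("B must be >= 1")
  x <- scale_matrix(battery)
  s <- battery_summary(x)
  m_obs <- sum(s$violations)
  m_null <- with_seed(substream(seed, paste0("shuffle_", scheme)), {
    vapply(seq_len(B), function(b) fom_matrix(shuffle_matrix(x, scheme)),
           integer(1))
  })
  p <- (1 + sum(m_null <= m_obs)) / (1 + B)
  structure(list(violations = s$violations, figure_of_merit = m_obs,
                 null_values = m_null, p = p, scheme = scheme,
                 B = B, seed = seed, n_children = nrow(x)),
            class = "tom_scaling")
}

#' @export
print.tom_scaling <- function(x, ...) {
  cat("Set-inclusion scaling test (", x$n_children, " children)\n", sep = "")
  cat("Successive violations:",
      paste(sprintf("%s: %d", names(x$violations), x$violations),
            collapse = ", "), "\n")
  cat("Figure of merit M =", x$figure_of_merit,
      "(0 = perfect hierarchy; lower is better)\n")
  cat(sprintf("Shuffle null (%s, B = %d): mean M_b = %.1f, p = %.4g\n",
              x$scheme, x$B, mean(x$null_values), x$p))
  invisible(x)
}

#' @export
plot.tom_scaling <- function(x, ...) {
  graphics::hist(x$null_values, breaks = 30, col = "grey85",
                 main = sprintf("Shuffle null (%s)", x$scheme),
                 xlab = "figure of merit M", ...)
  graphics::abline(v = x$figure_of_merit, col = "red3", lwd = 2)
  graphics::mtext(sprintf("observed M = %d, p = %.3g",
                          x$figure_of_merit, x$p), col = "red3")
  invisible(x)
}

#' Inclusion-diagram data
#'
#' Areas and successive overlaps for a set-inclusion diagram of the four
#' scale tasks (each task a square with area |G_k|; overlap of successive
#' squares |G_k intersect G_(k+1)|), exported as plain data for plotting.
#'
#' @param battery A [tom_battery] or binary matrix covering tasks 1-4.
#' @return data.frame with columns `task`, `pass_count`,
#'   `overlap_with_next` (NA for the last task).
#' @export
inclusion_diagram <- function(battery) {
  g <- pass_sets(battery)
  K <- length(g)
  data.frame(task = TOM_SCALE_TASKS[seq_len(K)],
             pass_count = unname(lengths(g)),
             overlap_with_next = c(vapply(seq_len(K - 1), function(k)
               length(intersect(g[[k]], g[[k + 1]])), integer(1)), NA))
}
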
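#' Synthetic cohort generator configuration
#'
#' Parameters of the latent-ability model behind the synthetic battery.
#' Child i gets ability
#' `a_i = beta_age * (age_i - mean(age)) + beta_gender * girl_i +
#'  beta_siblings * n_siblings_i + Normal(0, ability_sd)`,
#' and passes task k with probability
#' `guess + (1 - guess - slip) * plogis(a_i - d_k)` (four-parameter
#' IRT-style slip/guess floor and ceiling), responses independent Bernoulli
#' across tasks given the ability.
#'
#' The defaults are calibrated to the studied cohort: 76 children aged
#' 73-103 months, and task difficulties chosen so the expected pass rates
#' for the four scale tasks equal the observed proportions 62/76, 56/76,
#' 48/76 and 36/76 (with EFB/BE kept hardest to respect the ordered
#' difficulty of the scale).
#'
#' @param n_children Number of children.
#' @param age_range_months Integer (low, high); ages sampled uniformly on
#'   whole months.
#' @param p_girl Probability of gender code 1 (girl).
#' @param sibling_rate Poisson mean for sibling count (truncated at 6).
#' @param task_difficulties Six non-decreasing reals d_k.
#' @param beta_age Log-odds per month of (centered) age.
#' @param beta_gender Log-odds girl minus boy.
#' @param beta_siblings Log-odds per sibling.
#' @param slip,guess Probabilities of failing despite ability / passing
#'   despite inability; `slip + guess < 1`.
#' @param ability_sd SD of the child-level latent noise.
#' @param seed Integer seed; every generator draw derives from it through
#'   named substreams, so outputs are bit-identical across runs and
#'   unaffected by the order in which operations are called.
#' @return List of class `tom_sim_config`.
#' @export
sim_config <- function(n_children = 76,
                       age_range_months = c(73, 103),
                       p_girl = 0.5,
                       sibling_rate = 1.2,
                       task_difficulties = c(-2.168, -1.382, -0.626,
                                             0.315, 0.510, 0.686),
                       beta_age = 0.05,
                       beta_gender = 0.5,
                       beta_siblings = 0,
                       slip = 0.08,
                       guess = 0.05,
                       ability_sd = 1,
                       seed = 1L) {
  cfg <- list(n_children = as.integer(n_children),
              age_range_months = as.numeric(age_range_months),
              p_girl = p_girl, sibling_rate = sibling_rate,
              task_difficulties = as.numeric(task_difficulties),
              beta_age = beta_age, beta_gender = beta_gender,
              beta_siblings = beta_siblings,
              slip = slip, guess = guess, ability_sd = ability_sd,
              seed = as.integer(seed))
  if (cfg$n_children < 1) stop("n_children must be >= 1")
  if (length(cfg$age_range_months) != 2 ||
      diff(cfg$age_range_months) < 0 || cfg$age_range_months[1] <= 0)
    stop("age_range_months must be a positive (low, high) pair")
  if (cfg$p_girl < 0 || cfg$p_girl > 1) stop("p_girl must be in [0, 1]")
  if (length(cfg$task_difficulties) != 6)
    stop("task_difficulties must have length 6")
  if (is.unsorted(cfg$task_difficulties))
    stop("task_difficulties must be non-decreasing (ordered scale)")
  if (cfg$slip < 0 || cfg$guess < 0 || cfg$slip + cfg$guess >= 1)
    stop("need 0 <= slip, guess and slip + guess < 1")
  if (cfg$ability_sd < 0) stop("ability_sd must be >= 0")
  class(cfg) <- "tom_sim_config"
  cfg
}

# Deterministic substream seed: a 32-bit-safe hash of (seed, label), so
# adding or re-ordering generator stages never perturbs other stages' draws.
substream <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate synthetic child covariates
#'
#' Ages uniform on whole months in `age_range_months`; gender
#' Bernoulli(`p_girl`); sibling counts Poisson(`sibling_rate`) truncated at
#' 6; birth order uniform on 1..siblings+1; the three CBQ-style temperament
#' scores standard normal. Deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return data.frame of covariates incl. `disambiguation_index`.
#' @export
simulate_children <- function(config) {
  stopifnot(inherits(config, "tom_sim_config"))
  n <- config$n_children
  with_seed(substream(config$seed, "children"), {
    lo <- config$age_range_months[1]; hi <- config$age_range_months[2]
    covs <- data.frame(
      age_months = sample(seq(lo, hi), n, replace = TRUE),
      gender = stats::rbinom(n, 1, config$p_girl),
      n_siblings = pmin(stats::rpois(n, config$sibling_rate), 6L))
    covs$birth_order <- vapply(covs$n_siblings + 1L,
                               function(m) sample.int(m, 1L), integer(1))
    covs$surgency <- stats::rnorm(n)
    covs$negative_affect <- stats::rnorm(n)
    covs$effortful_control <- stats::rnorm(n)
    validate_covariates(covs, n)
  })
}

# Latent abilities given covariates; age centered at the sample mean so
# beta_age has the same meaning whatever the age window.
latent_ability <- function(covs, config, noise = TRUE) {
  a <- config$beta_age * (covs$age_months - mean(covs$age_months)) +
    config$beta_gender * covs$gender +
    config$beta_siblings * covs$n_siblings
  if (noise && config$ability_sd > 0)
    a <- a + stats::rnorm(nrow(covs), 0, config$ability_sd)
  a
}

#' Generate battery responses under the slip/guess model
#'
#' @param covs Covariates from [simulate_children] (or any validated
#'   covariate data.frame).
#' @param config A [sim_config].
#' @return 6-column binary response matrix; deterministic given
#'   `config$seed`.
#' @export
simulate_responses <- function(covs, config) {
  stopifnot(inherits(config, "tom_sim_config"))
  with_seed(substream(config$seed, "responses"), {
    a <- latent_ability(covs, config)
    p <- config$guess + (1 - config$guess - config$slip) *
      stats::plogis(outer(a, config$task_difficulties, `-`))
    m <- matrix(stats::rbinom(length(p), 1L, p), nrow(p),
                dimnames = list(NULL, TOM_TASKS))
    m
  })
}

#' Generate a perfectly scaled (Guttman) response matrix
#'
#' Child i passes task k iff its latent ability reaches the task's
#' difficulty, with no Bernoulli noise: the pass sets are exactly nested,
#' G_6 in G_5 in ... in G_1, and the figure of merit is 0 on every draw.
#'
#' @inheritParams simulate_responses
#' @return 6-column binary matrix.
#' @export
perfect_guttman <- function(covs, config) {
  stopifnot(inherits(config, "tom_sim_config"))
  with_seed(substream(config$seed, "responses"), {
    a <- latent_ability(covs, config)
    m <- 1L * outer(a, config$task_difficulties, `>=`)
    dimnames(m) <- list(NULL, TOM_TASKS)
    storage.mode(m) <- "integer"
    m
  })
}

#' Simulate a complete battery
#'
#' @param config A [sim_config].
#' @param guttman If TRUE use [perfect_guttman] instead of the noisy
#'   Bernoulli responses.
#' @return A [tom_battery] with covariates.
#' @export
simulate_battery <- function(config = sim_config(), guttman = FALSE) {
  covs <- simulate_children(config)
  resp <- if (guttman) perfect_guttman(covs, config)
          else simulate_responses(covs, config)
  tom_battery(resp, covs)
}

#' Read / write a generator configuration
#'
#' Flat key-value YAML; every field of [sim_config].
#' @param path File path.
#' @return `read_sim_config`: a validated [sim_config].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "tom_sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.tom_sim_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_children, "children, ages",
      paste(x$age_range_months, collapse = "-"), "months\n")
  cat("  difficulties:", paste(round(x$task_difficulties, 3),
                               collapse = ", "), "\n")
  cat(sprintf("  beta_age=%g/mo beta_gender=%g beta_siblings=%g\n",
              x$beta_age, x$beta_gender, x$beta_siblings))
  cat(sprintf("  slip=%g guess=%g ability_sd=%g seed=%d\n",
              x$slip, x$guess, x$ability_sd, x$seed))
  invisible(x)
}
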
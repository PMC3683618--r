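# Independent brute-force oracles used to freeze expected values.

# All permutations of a vector, as a list.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# Violation count by direct looping (independent of the package's
# vectorised implementation).
oracle_fom <- function(x) {
  s <- 0L
  for (k in 2:ncol(x)) s <- s + sum(x[, k] == 1 & x[, k - 1] == 0)
  s
}

# Exact two-sided permutation p for a correlation: proportion of ALL
# orderings of y whose |r| reaches the observed |r|.
exact_perm_cor_p <- function(x, y) {
  r_obs <- abs(stats::cor(x, y))
  ps <- all_perms(y)
  mean(vapply(ps, function(yy) abs(stats::cor(x, yy)) >= r_obs - 1e-12,
              logical(1)))
}

# Exact one-sided within-child shuffle p: enumerate every combination of
# row permutations ((K!)^n surrogates) and count M_b <= M_obs.
exact_within_child_p <- function(x) {
  m_obs <- oracle_fom(x)
  rp <- all_perms(seq_len(ncol(x)))
  idx <- do.call(expand.grid, rep(list(seq_along(rp)), nrow(x)))
  hits <- apply(idx, 1, function(ii) {
    xx <- t(sapply(seq_len(nrow(x)), function(i) x[i, rp[[ii[i]]]]))
    oracle_fom(xx) <= m_obs
  })
  mean(hits)
}

# Is the pass-set chain fully nested (G_(k+1) subset of G_k for all k)?
nested_chain <- function(x) {
  for (k in 2:ncol(x)) if (any(x[, k] == 1 & x[, k - 1] == 0)) return(FALSE)
  TRUE
}

# A small valid covariate table for hand-built batteries.
toy_covariates <- function(n, seed = 99) {
  cfg <- sim_config(n_children = n, seed = seed)
  simulate_children(cfg)
}
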
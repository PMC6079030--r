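# Shared fixtures, built once per test run.

default_design <- function() {
  if (is.null(.fixture_env$design)) {
    .fixture_env$design <- generate_design(design_spec(seed = 1))
  }
  .fixture_env$design
}

# small fitted cohort reused across group-stat tests
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    d <- default_design()
    co <- simulate_cohort(cohort_spec(n_agents = 25, seed = 42), d)
    co$glm_fits <- fit_influence_cohort(co$trials)
    co$rl_fits <- fit_rl_cohort(co$trials, grid_step = 0.001)
    .fixture_env$cohort <- co
  }
  .fixture_env$cohort
}

.fixture_env <- new.env(parent = emptyenv())

# Independent brute-force logistic MLE: zooming dense grid over a
# coefficient box. Never calls glm machinery; log-likelihood coded directly.
grid_logistic_mle <- function(X, y, box = 8, points = 9, levels = 16) {
  k <- ncol(X)
  centre <- rep(0, k)
  width <- rep(2 * box, k)
  best <- NULL
  for (lev in seq_len(levels)) {
    axes <- lapply(seq_len(k), function(j) {
      seq(centre[j] - width[j] / 2, centre[j] + width[j] / 2,
          length.out = points)
    })
    cand <- as.matrix(expand.grid(axes))
    eta <- X %*% t(cand)
    ll <- colSums(y * eta - log1p(exp(eta)))
    i <- which.max(ll)
    centre <- cand[i, ]
    best <- list(coefficients = centre, log_lik = ll[i])
    # shrink the box around the current optimum
    width <- width * 2 / (points - 1) * 2
  }
  best
}

# direct log-likelihood of a logistic model
loglik_logistic <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}
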
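# Internal logistic-regression workhorses shared by the influence model and
# the RL grid fit. glm.fit does the IRLS; a Jeffreys-penalized (Firth) fit
# is the fallback under (quasi-)complete separation, where ordinary ML
# estimates diverge.

logit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Fit y ~ X (X includes the intercept column). Returns coefficients,
# log-likelihood, convergence and separation flags, and the method used.
fit_logistic <- function(X, y, firth_fallback = TRUE, max_iter = 100L,
                         tol = 1e-8) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter))
  )
  coefs <- fit$coefficients
  rank_deficient <- any(is.na(coefs))
  mu <- fit$fitted.values
  # diverging coefficients with fitted probabilities pinned at 0/1 signal
  # (quasi-)complete separation
  separated <- !rank_deficient &&
    max(abs(coefs)) > 15 &&
    any(mu < 1e-6 | mu > 1 - 1e-6)
  method <- "ml"
  if (separated && firth_fallback) {
    ff <- fit_firth(X, y, max_iter = max_iter, tol = tol)
    coefs <- ff$coefficients
    method <- "firth"
    ll <- logit_loglik(coefs, X, y)
    converged <- ff$converged
  } else {
    ll <- -fit$deviance / 2
    converged <- fit$converged && !rank_deficient
  }
  list(
    coefficients = coefs,
    log_lik = ll,
    converged = converged,
    separated = separated,
    rank_deficient = rank_deficient,
    method = method
  )
}

# Firth-type penalized logistic regression: IRLS on the modified score
# U*(beta) = X' (y - mu + h (1/2 - mu)), h the hat-matrix diagonal.
fit_firth <- function(X, y, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * X) * w
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% score)
    # step-halving for stability
    for (k in 0:10) {
      cand <- beta + step / 2^k
      if (all(is.finite(stats::plogis(drop(X %*% cand))))) {
        break
      }
    }
    beta_new <- cand
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(coefficients = beta, converged = converged)
}
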
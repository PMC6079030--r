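#' Check response variability of a decision sequence
#'
#' Participants who press (nearly) the same button throughout the task give
#' a logistic model nothing to fit; they are excluded. The check fails when
#' the minority response class has fewer than `min_minority` occurrences.
#'
#' @param decisions Binary vector of decisions.
#' @param min_minority Minimum size of the minority class. Default 3.
#' @return A list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
#' @examples
#' check_response_variability(rep(1, 75))$pass
check_response_variability <- function(decisions, min_minority = 3) {
  stopifnot(length(decisions) >= 1, all(decisions %in% c(0, 1)))
  n1 <- sum(decisions == 1)
  minority <- min(n1, length(decisions) - n1)
  if (minority == 0) {
    list(pass = FALSE, reason = "uniform button press")
  } else if (minority < min_minority) {
    list(pass = FALSE,
         reason = sprintf("near-uniform button press (minority class %d < %d)",
                          minority, min_minority))
  } else {
    list(pass = TRUE, reason = NA_character_)
  }
}

#' Fit the trial-wise feedback-influence model for one participant
#'
#' Maximum-likelihood fit of the logistic decision model
#' `logit P(Decision = 1) = beta_cfb * cFB + beta_accfb * accFB +
#' beta_oc * OC + beta_0`,
#' where cFB is the current trial's feedback code, accFB the rescaled
#' running feedback sum up to the preceding trial, and OC the rescaled
#' objective creativity. Quasi-complete separation is detected and the fit
#' falls back to a Jeffreys-penalized (Firth) estimate, flagged as such.
#'
#' @param data A single participant's trial table with columns `decision`,
#'   `cfb`, `accfb`, `oc` (see [add_predictors()]).
#' @param min_minority Response-variability threshold; see
#'   [check_response_variability()].
#' @return An object of class `influence_fit` with elements `coefficients`
#'   (`beta_cfb`, `beta_accfb`, `beta_oc`, `beta_0`), `log_lik`,
#'   `converged`, `separated`, `method`, `rank_deficient`, `n`.
#' @export
#' @examples
#' design <- generate_design(design_spec(seed = 1))
#' trials <- simulate_agent(agent_params(0.4), design, seed = 7)
#' fit_influence(add_predictors(trials))
fit_influence <- function(data, min_minority = 3) {
  stopifnot(all(c("decision", "cfb", "accfb", "oc") %in% names(data)))
  vc <- check_response_variability(data$decision, min_minority)
  if (!vc$pass) {
    stop("participant excluded: ", vc$reason, call. = FALSE)
  }
  X <- cbind(cfb = data$cfb, accfb = data$accfb, oc = data$oc,
             intercept = 1)
  fit <- fit_logistic(X, data$decision)
  if (fit$rank_deficient) {
    warning("design matrix is rank deficient; some coefficients are ",
            "inestimable (NA)", call. = FALSE)
  } else if (fit$separated) {
    sep_dir <- which.max(abs(fit$coefficients[1:3]))
    warning("quasi-complete separation detected (largest coefficient: ",
            c("cfb", "accfb", "oc")[sep_dir],
            "); reporting Jeffreys-penalized fit", call. = FALSE)
  }
  coefs <- fit$coefficients
  names(coefs) <- c("beta_cfb", "beta_accfb", "beta_oc", "beta_0")
  structure(
    list(coefficients = coefs, log_lik = fit$log_lik,
         converged = fit$converged, separated = fit$separated,
         rank_deficient = fit$rank_deficient, method = fit$method,
         n = nrow(data)),
    class = "influence_fit"
  )
}

#' @export
print.influence_fit <- function(x, ...) {
  cat("<influence_fit> n = ", x$n, ", logLik = ", signif(x$log_lik, 6),
      if (x$method == "firth") " (Firth-penalized)", "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
#' @method tidy influence_fit
tidy.influence_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @export
#' @method glance influence_fit
glance.influence_fit <- function(x, ...) {
  tibble::tibble(
    log_lik = x$log_lik, n = x$n, converged = x$converged,
    separated = x$separated, method = x$method
  )
}

#' Fit the feedback-influence model across a cohort
#'
#' Applies the exclusion rule and [fit_influence()] to every participant in
#' a trial table. Predictor columns are built on the fly when absent.
#'
#' @param trials Trial table with columns `participant`, `trial`,
#'   `valence`, `oc_level`, `decision` (predictors `cfb`, `accfb`, `oc`
#'   added via [add_predictors()] when missing).
#' @param min_minority Response-variability threshold.
#' @return A tibble with one row per participant: coefficient estimates,
#'   `log_lik`, `converged`, `separated`, `method`, `excluded`, `reason`.
#'   Excluded participants keep their row with `NA` coefficients.
#' @export
fit_influence_cohort <- function(trials, min_minority = 3) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  if (!all(c("cfb", "accfb", "oc") %in% names(trials))) {
    trials <- add_predictors(trials)
  }
  trials |>
    dplyr::group_by(participant) |>
    dplyr::group_modify(function(d, key) {
      vc <- check_response_variability(d$decision, min_minority)
      if (!vc$pass) {
        return(tibble::tibble(
          beta_cfb = NA_real_, beta_accfb = NA_real_, beta_oc = NA_real_,
          beta_0 = NA_real_, log_lik = NA_real_, converged = NA,
          separated = NA, method = NA_character_,
          excluded = TRUE, reason = vc$reason
        ))
      }
      f <- suppressWarnings(fit_influence(d, min_minority))
      tibble::tibble(
        beta_cfb = f$coefficients[["beta_cfb"]],
        beta_accfb = f$coefficients[["beta_accfb"]],
        beta_oc = f$coefficients[["beta_oc"]],
        beta_0 = f$coefficients[["beta_0"]],
        log_lik = f$log_lik, converged = f$converged,
        separated = f$separated, method = f$method,
        excluded = FALSE, reason = NA_character_
      )
    }) |>
    dplyr::ungroup()
}
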
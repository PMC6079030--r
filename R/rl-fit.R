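# VSP_t for every trial at a given alpha, via the recursive filter
# vsp_t = (1 - alpha) * vsp_{t-1} + alpha * fb_t, vsp_0 = 0.
vsp_series <- function(fb, alpha) {
  if (alpha == 0) return(rep(0, length(fb)))
  as.numeric(stats::filter(alpha * fb, 1 - alpha, method = "recursive"))
}

rl_loglik_at_alpha <- function(alpha, fb, oc, decision) {
  vsp <- vsp_series(fb, alpha)
  X <- cbind(vsp = vsp, oc = oc, intercept = 1)
  fit <- fit_logistic(X, decision)
  list(ll = fit$log_lik, fit = fit, vsp = vsp)
}

#' Grid-search maximum-likelihood fit of the self-protection RL model
#'
#' For each candidate learning rate alpha on a grid over \[0, 1\], the VSP
#' trajectory is rebuilt from the reverse-coded feedback and the decision
#' model `logit P(D = 1) = beta_vsp * VSP_t + beta_oc * OC + beta_0` is fit
#' by maximum likelihood (profile likelihood over alpha). The grid alpha
#' with the highest log-likelihood is returned, ties broken toward the
#' smaller alpha.
#'
#' By default a coarse scan (step 0.01) locates the optimum and the target
#' resolution (`grid_step`, default 0.0001) is applied in a window of one
#' coarse cell around it; `refine = FALSE` forces the exhaustive fine grid.
#'
#' A flat profile likelihood (range below `flat_tol`) marks the fit as
#' non-identifiable (e.g. an agent blind to VSP) and returns the tie-break
#' alpha of 0.
#'
#' @param data One participant's trial table with columns `valence`,
#'   `oc_level`, `decision` (and `trial` for ordering).
#' @param grid_step Learning-rate grid resolution. Default 0.0001.
#' @param refine Use the coarse-scan + refinement strategy. Default TRUE.
#' @param vsp_timing `"current"` pairs trial t's decision with VSP updated
#'   through trial t's feedback (`VSP_t`, the default); `"previous"` uses
#'   `VSP_{t-1}`, exposed for sensitivity analysis.
#' @param min_minority Response-variability threshold.
#' @param flat_tol Likelihood range below which the profile is flat.
#' @return An object of class `rl_fit`: `alpha_hat`, `coefficients`
#'   (`beta_vsp`, `beta_oc`, `beta_0`), `max_log_lik`, `violator`
#'   (`beta_vsp > 0`), `identifiable`, `separated`, `method`, `grid_step`,
#'   `vsp` (trajectory at `alpha_hat`), `n`.
#' @export
#' @examples
#' design <- generate_design(design_spec(seed = 1))
#' trials <- simulate_agent(agent_params(0.3, beta_vsp = -3), design, seed = 2)
#' fit <- fit_rl(trials, grid_step = 0.001)
#' fit$alpha_hat
fit_rl <- function(data, grid_step = 1e-4, refine = TRUE,
                   vsp_timing = c("current", "previous"),
                   min_minority = 3, flat_tol = 1e-6) {
  vsp_timing <- match.arg(vsp_timing)
  stopifnot(all(c("valence", "oc_level", "decision") %in% names(data)),
            grid_step > 0, grid_step <= 1)
  if ("trial" %in% names(data)) data <- data[order(data$trial), ]
  vc <- check_response_variability(data$decision, min_minority)
  if (!vc$pass) stop("participant excluded: ", vc$reason, call. = FALSE)

  fb <- reverse_code_fb(data$valence)
  oc <- rescale_oc(data$oc_level)
  decision <- data$decision
  shift <- function(v) if (vsp_timing == "previous") c(0, v[-length(v)]) else v

  ll_at <- function(a) {
    vsp <- shift(vsp_series(fb, a))
    fit <- fit_logistic(cbind(vsp = vsp, oc = oc, intercept = 1), decision)
    fit$log_lik
  }
  eval_grid <- function(alphas) vapply(alphas, ll_at, numeric(1))

  coarse_step <- max(grid_step, 0.01)
  if (refine && grid_step < coarse_step) {
    coarse <- seq(0, 1, by = coarse_step)
    ll_c <- eval_grid(coarse)
    flat <- (max(ll_c) - min(ll_c)) < flat_tol
    best_c <- coarse[which.max(ll_c)]   # which.max takes the first (smallest)
    lo <- max(0, best_c - coarse_step)
    hi <- min(1, best_c + coarse_step)
    fine <- seq(lo, hi, by = grid_step)
    ll_f <- eval_grid(fine)
    if (flat) {
      alpha_hat <- 0
      identifiable <- FALSE
    } else {
      alpha_hat <- fine[which.max(ll_f)]
      identifiable <- TRUE
    }
    max_ll_grid <- max(ll_f)
  } else {
    grid <- seq(0, 1, by = grid_step)
    ll_g <- eval_grid(grid)
    flat <- (max(ll_g) - min(ll_g)) < flat_tol
    if (flat) {
      alpha_hat <- 0
      identifiable <- FALSE
    } else {
      alpha_hat <- grid[which.max(ll_g)]
      identifiable <- TRUE
    }
    max_ll_grid <- max(ll_g)
  }

  vsp <- shift(vsp_series(fb, alpha_hat))
  final <- fit_logistic(cbind(vsp = vsp, oc = oc, intercept = 1), decision)
  coefs <- final$coefficients
  names(coefs) <- c("beta_vsp", "beta_oc", "beta_0")
  structure(
    list(alpha_hat = alpha_hat, coefficients = coefs,
         max_log_lik = final$log_lik,
         violator = unname(coefs["beta_vsp"] > 0),
         identifiable = identifiable,
         separated = final$separated, method = final$method,
         grid_step = grid_step, vsp = vsp, n = length(decision)),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit> alpha_hat = ", x$alpha_hat,
      ", logLik = ", signif(x$max_log_lik, 6),
      if (x$violator) ", VIOLATOR (beta_vsp > 0)",
      if (!x$identifiable) ", non-identifiable",
      "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
#' @method tidy rl_fit
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", names(x$coefficients)),
    estimate = c(x$alpha_hat, unname(x$coefficients))
  )
}

#' @export
#' @method glance rl_fit
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    alpha_hat = x$alpha_hat, max_log_lik = x$max_log_lik,
    violator = x$violator, identifiable = x$identifiable,
    separated = x$separated, method = x$method, n = x$n
  )
}

#' Flag participants whose fitted policy contradicts self-protection
#'
#' The model assumes high self-protection value suppresses favorable
#' partner evaluation; a fitted `beta_vsp > 0` (favorable evaluation under
#' high VSP) violates that assumption and excludes the participant from
#' group analyses.
#'
#' @param fit An `rl_fit`, or a numeric `beta_vsp` value.
#' @return Logical.
#' @export
flag_violator <- function(fit) {
  b <- if (inherits(fit, "rl_fit")) fit$coefficients[["beta_vsp"]] else fit
  unname(b > 0)
}

#' Fit the RL model across a cohort
#'
#' @param trials Trial table with `participant`, `trial`, `valence`,
#'   `oc_level`, `decision`.
#' @inheritParams fit_rl
#' @return A tibble with one row per participant: `alpha_hat`, `beta_vsp`,
#'   `beta_oc`, `beta_0`, `max_log_lik`, `violator`, `identifiable`,
#'   `excluded`, `reason`.
#' @export
fit_rl_cohort <- function(trials, grid_step = 1e-4, refine = TRUE,
                          vsp_timing = c("current", "previous"),
                          min_minority = 3) {
  vsp_timing <- match.arg(vsp_timing)
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  trials |>
    dplyr::group_by(participant) |>
    dplyr::group_modify(function(d, key) {
      vc <- check_response_variability(d$decision, min_minority)
      if (!vc$pass) {
        return(tibble::tibble(
          alpha_hat = NA_real_, beta_vsp = NA_real_, beta_oc = NA_real_,
          beta_0 = NA_real_, max_log_lik = NA_real_, violator = NA,
          identifiable = NA, excluded = TRUE, reason = vc$reason
        ))
      }
      f <- suppressWarnings(
        fit_rl(d, grid_step = grid_step, refine = refine,
               vsp_timing = vsp_timing, min_minority = min_minority)
      )
      tibble::tibble(
        alpha_hat = f$alpha_hat,
        beta_vsp = f$coefficients[["beta_vsp"]],
        beta_oc = f$coefficients[["beta_oc"]],
        beta_0 = f$coefficients[["beta_0"]],
        max_log_lik = f$max_log_lik, violator = f$violator,
        identifiable = f$identifiable, excluded = FALSE,
        reason = NA_character_
      )
    }) |>
    dplyr::ungroup()
}

#' VSP-conditioned partner-derogation / enhancement bias analysis
#'
#' For each non-violator participant, trial-wise decision probabilities are
#' rebuilt from the fitted RL policy and averaged separately over high-VSP
#' (`VSP > 0`) and low-VSP (`VSP < 0`) trials; trials with VSP exactly 0
#' belong to neither set, and a participant contributes to a set only when
#' they have at least one qualifying trial. At the group level each set's
#' mean probabilities are tested against the chance level 0.5 with a
#' one-sample Wilcoxon signed-rank test, plus a paired Wilcoxon between
#' sets. A below-chance high-VSP mean indicates partner derogation; an
#' above-chance low-VSP mean would indicate partner enhancement.
#'
#' @param rl_fits Cohort fit table from [fit_rl_cohort()].
#' @param trials The trial table the fits came from.
#' @param vsp_timing VSP/decision pairing, as in [fit_rl()].
#' @return An object of class `vsp_bias`: `per_participant` (tibble with
#'   `participant`, `mean_p_high`, `mean_p_low`, trial counts), and
#'   `tests` (tibble with the two one-sample tests and the paired test).
#' @export
vsp_bias_analysis <- function(rl_fits, trials,
                              vsp_timing = c("current", "previous")) {
  vsp_timing <- match.arg(vsp_timing)
  keep <- rl_fits[!rl_fits$excluded & !is.na(rl_fits$violator) &
                    !rl_fits$violator, ]
  if (nrow(keep) == 0L) stop("no non-violator participants", call. = FALSE)
  per <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    row <- keep[i, ]
    d <- trials[trials$participant == row$participant, ]
    d <- d[order(d$trial), ]
    vsp <- vsp_series(reverse_code_fb(d$valence), row$alpha_hat)
    if (vsp_timing == "previous") vsp <- c(0, vsp[-length(vsp)])
    p <- stats::plogis(row$beta_vsp * vsp + row$beta_oc *
                         rescale_oc(d$oc_level) + row$beta_0)
    tibble::tibble(
      participant = row$participant,
      n_high = sum(vsp > 0), n_low = sum(vsp < 0),
      mean_p_high = if (any(vsp > 0)) mean(p[vsp > 0]) else NA_real_,
      mean_p_low = if (any(vsp < 0)) mean(p[vsp < 0]) else NA_real_
    )
  })
  hi <- per$mean_p_high[!is.na(per$mean_p_high)]
  lo <- per$mean_p_low[!is.na(per$mean_p_low)]
  tests <- dplyr::bind_rows(
    if (length(hi) >= 5)
      dplyr::mutate(wilcoxon_signed_rank(hi, mu0 = 0.5),
                    analysis = "high_vsp_vs_chance"),
    if (length(lo) >= 5)
      dplyr::mutate(wilcoxon_signed_rank(lo, mu0 = 0.5),
                    analysis = "low_vsp_vs_chance"),
    {
      both <- per[!is.na(per$mean_p_high) & !is.na(per$mean_p_low), ]
      if (nrow(both) >= 5)
        dplyr::mutate(
          wilcoxon_signed_rank(both$mean_p_high - both$mean_p_low, mu0 = 0),
          analysis = "high_minus_low_paired"
        )
    }
  )
  structure(list(per_participant = per, tests = tests), class = "vsp_bias")
}

#' @export
print.vsp_bias <- function(x, ...) {
  cat("<vsp_bias> ", nrow(x$per_participant), " participants\n", sep = "")
  print(x$tests)
  invisible(x)
}
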
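#' Parameters of a synthetic participant
#'
#' A generative agent follows the package's own decision model: its
#' self-protection value is updated by the delta rule with learning rate
#' `alpha`, and each partner-evaluation decision is Bernoulli with
#' probability `plogis(beta_vsp * VSP_t + beta_oc * OC + beta_0)`.
#' Self-protective agents have `beta_vsp < 0` (high VSP suppresses a
#' "creative" rating).
#'
#' @param alpha Learning rate in [0, 1].
#' @param beta_vsp Policy weight on VSP.
#' @param beta_oc Policy weight on rescaled objective creativity.
#' @param beta_0 Policy intercept.
#' @param age Age in years (carried through for group analyses).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha, beta_vsp = -3, beta_oc = 1, beta_0 = 0,
                         age = NA_real_) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(
    list(alpha = alpha, beta_vsp = beta_vsp, beta_oc = beta_oc,
         beta_0 = beta_0, age = age),
    class = "agent_params"
  )
}

#' Simulate one agent on a task design
#'
#' VSP is updated through the current trial's (reverse-coded) feedback
#' before the evaluation decision, i.e. trial t's decision uses `VSP_t`.
#'
#' @param params An [agent_params()].
#' @param design A `task_design` from [generate_design()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return A tibble with one row per trial: `trial`, `valence`, `oc_level`,
#'   `decision` (1 = rated the partner's artwork creative), plus the latent
#'   `vsp` and decision probability `p` for diagnostics.
#' @export
simulate_agent <- function(params, design, seed = 1L) {
  stopifnot(inherits(params, "agent_params"))
  design <- design[order(design$trial), ]
  fb <- reverse_code_fb(design$valence)
  traj <- update_vsp(fb, params$alpha)
  vsp_t <- traj$vsp[-1L]       # VSP updated through the current trial
  oc <- rescale_oc(design$oc_level)
  p <- stats::plogis(params$beta_vsp * vsp_t + params$beta_oc * oc +
                       params$beta_0)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  decision <- stats::rbinom(length(p), 1L, p)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tibble::tibble(
    trial = design$trial,
    valence = design$valence,
    oc_level = design$oc_level,
    decision = decision,
    vsp = vsp_t,
    p = p
  )
}

#' Specify a synthetic developmental cohort
#'
#' Ages are uniform over `age_range`; the learning rate declines linearly
#' with age (`alpha = alpha_intercept + alpha_age_slope * (age - min age)`,
#' plus Gaussian noise, clipped to [0, 1]), emulating the developmental
#' decrease in reliance on the most recent feedback. Policy weights are
#' drawn from Gaussians; the default `beta_vsp` mean of -3 makes agents
#' self-protective on average, with an occasional positive draw playing the
#' role of a model violator.
#'
#' @param n_agents Number of agents.
#' @param age_range Two-element numeric vector, years. Default `c(10, 25)`.
#' @param alpha_age_slope Change in alpha per year of age. Default -0.029.
#' @param alpha_intercept Mean alpha at the youngest age. Default 0.7.
#' @param alpha_noise_sd SD of the alpha perturbation. Default 0.1.
#' @param beta_vsp_mean,beta_vsp_sd,beta_oc_mean,beta_oc_sd,beta_0_mean,beta_0_sd
#'   Policy-weight distributions.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_agents = 60,
                        age_range = c(10, 25),
                        alpha_age_slope = -0.029,
                        alpha_intercept = 0.7,
                        alpha_noise_sd = 0.1,
                        beta_vsp_mean = -3, beta_vsp_sd = 1,
                        beta_oc_mean = 1, beta_oc_sd = 0.5,
                        beta_0_mean = 0, beta_0_sd = 0.5,
                        seed = 1L) {
  stopifnot(n_agents >= 1, length(age_range) == 2L,
            age_range[1] <= age_range[2], alpha_noise_sd >= 0)
  structure(
    list(n_agents = as.integer(n_agents), age_range = age_range,
         alpha_age_slope = alpha_age_slope,
         alpha_intercept = alpha_intercept,
         alpha_noise_sd = alpha_noise_sd,
         beta_vsp_mean = beta_vsp_mean, beta_vsp_sd = beta_vsp_sd,
         beta_oc_mean = beta_oc_mean, beta_oc_sd = beta_oc_sd,
         beta_0_mean = beta_0_mean, beta_0_sd = beta_0_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of agents on a shared design
#'
#' All agents see the same trial sequence, as in a fixed-sequence task.
#'
#' @param spec A [cohort_spec()].
#' @param design A `task_design`.
#' @return A list with two tibbles: `participants` (one row per agent:
#'   `participant`, `age`, `true_alpha`, `true_beta_vsp`, `true_beta_oc`,
#'   `true_beta_0`) and `trials` (`n_agents * n_trials` rows).
#' @export
#' @examples
#' design <- generate_design(design_spec(seed = 1))
#' cohort <- simulate_cohort(cohort_spec(n_agents = 5, seed = 2), design)
#' cohort$participants
simulate_cohort <- function(spec, design) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- globalenv()$.Random.seed
  set.seed(spec$seed)
  n <- spec$n_agents
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  alpha <- spec$alpha_intercept +
    spec$alpha_age_slope * (age - spec$age_range[1]) +
    stats::rnorm(n, 0, spec$alpha_noise_sd)
  alpha <- pmin(pmax(alpha, 0), 1)
  beta_vsp <- stats::rnorm(n, spec$beta_vsp_mean, spec$beta_vsp_sd)
  beta_oc <- stats::rnorm(n, spec$beta_oc_mean, spec$beta_oc_sd)
  beta_0 <- stats::rnorm(n, spec$beta_0_mean, spec$beta_0_sd)
  agent_seeds <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  participants <- tibble::tibble(
    participant = seq_len(n),
    age = age,
    true_alpha = alpha,
    true_beta_vsp = beta_vsp,
    true_beta_oc = beta_oc,
    true_beta_0 = beta_0
  )
  trials <- purrr::map_dfr(seq_len(n), function(i) {
    tr <- simulate_agent(
      agent_params(alpha[i], beta_vsp[i], beta_oc[i], beta_0[i], age[i]),
      design, seed = agent_seeds[i]
    )
    tr$participant <- i
    tr[, c("participant", "trial", "valence", "oc_level", "decision")]
  })
  list(participants = participants, trials = trials)
}

#' Specify a synthetic brain-age-behavior mediation cohort
#'
#' Emulates participant-level triads (age, an ROI parametric-modulation
#' estimate as mediator, a behavioral estimate as outcome) with a
#' configurable indirect effect `a_path * b_path`.
#'
#' @param n Number of participants (default 56).
#' @param a_path Effect of age on the mediator.
#' @param b_path Effect of the mediator on the outcome (age-adjusted).
#' @param c_prime Direct effect of age on the outcome.
#' @param mediator_noise_sd,outcome_noise_sd Residual SDs.
#' @param age_range Age range, years.
#' @param n_outliers,outlier_magnitude Optional outlier injection into the
#'   mediator, `outlier_magnitude` given in mediator residual SDs.
#' @param seed Integer seed.
#' @return An object of class `mediation_cohort_spec`.
#' @export
mediation_cohort_spec <- function(n = 56,
                                  a_path = 0.5, b_path = 0.4, c_prime = 0.1,
                                  mediator_noise_sd = 1,
                                  outcome_noise_sd = 1,
                                  age_range = c(10, 25),
                                  n_outliers = 0, outlier_magnitude = 6,
                                  seed = 1L) {
  stopifnot(n >= 4, mediator_noise_sd >= 0, outcome_noise_sd >= 0,
            n_outliers >= 0)
  structure(
    list(n = as.integer(n), a_path = a_path, b_path = b_path,
         c_prime = c_prime, mediator_noise_sd = mediator_noise_sd,
         outcome_noise_sd = outcome_noise_sd, age_range = age_range,
         n_outliers = as.integer(n_outliers),
         outlier_magnitude = outlier_magnitude, seed = as.integer(seed)),
    class = "mediation_cohort_spec"
  )
}

#' Simulate a mediation cohort
#'
#' `mediator = a_path * age + noise`;
#' `outcome = b_path * mediator + c_prime * age + noise`.
#'
#' @param spec A [mediation_cohort_spec()].
#' @return A tibble with columns `participant`, `age`, `mediator`,
#'   `outcome`, `is_injected_outlier`.
#' @export
simulate_mediation_cohort <- function(spec) {
  stopifnot(inherits(spec, "mediation_cohort_spec"))
  old <- globalenv()$.Random.seed
  set.seed(spec$seed)
  n <- spec$n
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  mediator <- spec$a_path * age + stats::rnorm(n, 0, spec$mediator_noise_sd)
  outcome <- spec$b_path * mediator + spec$c_prime * age +
    stats::rnorm(n, 0, spec$outcome_noise_sd)
  is_out <- rep(FALSE, n)
  if (spec$n_outliers > 0) {
    idx <- sample.int(n, spec$n_outliers)
    mediator[idx] <- mediator[idx] +
      sample(c(-1, 1), spec$n_outliers, replace = TRUE) *
        spec$outlier_magnitude * max(spec$mediator_noise_sd, 1e-12)
    is_out[idx] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tibble::tibble(
    participant = seq_len(n), age = age, mediator = mediator,
    outcome = outcome, is_injected_outlier = is_out
  )
}
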
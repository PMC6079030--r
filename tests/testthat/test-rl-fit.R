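test_that("grid MLE finds the generative learning rate on average", {
  d <- default_design()
  est <- vapply(1:20, function(i) {
    tr <- simulate_agent(agent_params(0.3, -3, 0, 0), d, seed = 200 + i)
    fit_rl(tr, grid_step = 0.001)$alpha_hat
  }, 1)
  expect_lt(abs(mean(est) - 0.3), 0.12)
})

test_that("alpha_hat lies on the grid and coefficients carry names", {
  d <- default_design()
  tr <- simulate_agent(agent_params(0.45, -3, 1, 0), d, seed = 61)
  f <- fit_rl(tr, grid_step = 0.001)
  expect_true(f$alpha_hat >= 0 && f$alpha_hat <= 1)
  expect_equal(f$alpha_hat * 1000, round(f$alpha_hat * 1000),
               tolerance = 1e-9)
  expect_named(f$coefficients, c("beta_vsp", "beta_oc", "beta_0"))
  expect_lte(f$max_log_lik, 0)
  expect_identical(nrow(tidy(f)), 4L)
  expect_s3_class(glance(f), "tbl_df")
})

test_that("refined search matches the exhaustive fine grid", {
  d <- default_design()
  for (s in 62:64) {
    tr <- simulate_agent(agent_params(0.35, -4, 0.5, 0), d, seed = s)
    a_ref <- fit_rl(tr, grid_step = 0.002, refine = TRUE)$alpha_hat
    a_full <- fit_rl(tr, grid_step = 0.002, refine = FALSE)$alpha_hat
    # both locate the same mode up to one coarse cell
    expect_lt(abs(a_ref - a_full), 0.01 + 1e-9)
  }
})

test_that("an all-neutral design leaves alpha non-identifiable", {
  neutral <- tibble::tibble(trial = 1:40, valence = "neutral",
                            oc_level = rep(1:5, 8))
  set.seed(65)
  neutral$decision <- rbinom(40, 1, plogis(0.8 * rescale_oc(neutral$oc_level)))
  f <- suppressWarnings(fit_rl(neutral, grid_step = 0.01))
  expect_false(f$identifiable)
  expect_identical(f$alpha_hat, 0)
})

test_that("violator flagging is the sign rule on beta_vsp", {
  expect_false(flag_violator(-2.1))
  expect_true(flag_violator(0.8))
  d <- default_design()
  # strongly self-protective cohort -> no violators
  co <- simulate_cohort(
    cohort_spec(n_agents = 10, beta_vsp_mean = -4, beta_vsp_sd = 0.3,
                seed = 66), d
  )
  fits <- fit_rl_cohort(co$trials, grid_step = 0.005)
  expect_identical(sum(fits$violator, na.rm = TRUE), 0L)
  # an anti-self-protective agent is flagged
  tr <- simulate_agent(agent_params(0.5, +4, 0, 0), d, seed = 67)
  f <- fit_rl(tr, grid_step = 0.005)
  expect_true(f$violator)
  expect_true(flag_violator(f))
})

test_that("fit_rl excludes invariant responders like the influence model", {
  d <- default_design()
  tr <- simulate_agent(agent_params(0.3, -3, 1, 0), d, seed = 68)
  tr$decision <- 1L
  expect_error(fit_rl(tr), "excluded")
})

test_that("derogation bias appears in high-VSP trials for negative beta_vsp", {
  co <- small_cohort()
  bias <- vsp_bias_analysis(co$rl_fits, co$trials)
  expect_true(all(bias$per_participant$mean_p_high <= 1 &
                    bias$per_participant$mean_p_high >= 0, na.rm = TRUE))
  hi <- bias$tests[bias$tests$analysis == "high_vsp_vs_chance", ]
  expect_lt(hi$estimate, 0.5)   # median below chance: derogation
  expect_lt(hi$p_value, 0.05)
  paired <- bias$tests[bias$tests$analysis == "high_minus_low_paired", ]
  expect_lt(paired$estimate, 0)
})

test_that("participants without qualifying trials drop from a bias cell", {
  # all-negative feedback: VSP > 0 on every trial for alpha > 0
  trials <- tibble::tibble(
    participant = 1L, trial = 1:10, valence = "negative",
    oc_level = rep(1:5, 2), decision = rep(c(0L, 1L), 5)
  )
  fits <- tibble::tibble(
    participant = 1L, alpha_hat = 0.3, beta_vsp = -2, beta_oc = 0.5,
    beta_0 = 0, max_log_lik = -5, violator = FALSE, identifiable = TRUE,
    excluded = FALSE, reason = NA_character_
  )
  bias <- vsp_bias_analysis(fits, trials)
  expect_identical(bias$per_participant$n_low, 0L)
  expect_true(is.na(bias$per_participant$mean_p_low))
  expect_false(is.na(bias$per_participant$mean_p_high))
})
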
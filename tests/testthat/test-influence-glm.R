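test_that("uniform and near-uniform responders are excluded", {
  expect_false(check_response_variability(rep(1, 75))$pass)
  expect_match(check_response_variability(rep(0, 75))$reason, "uniform")
  near <- c(rep(1, 74), 0)
  expect_false(check_response_variability(near)$pass)
  expect_match(check_response_variability(near)$reason, "near-uniform")
  mixed <- c(rep(1, 40), rep(0, 35))
  expect_true(check_response_variability(mixed)$pass)
  # threshold is configurable
  expect_true(check_response_variability(near, min_minority = 1)$pass)
})

test_that("an intercept-only fit reproduces the logit of the proportion", {
  set.seed(51)
  y <- rbinom(75, 1, 0.6)
  fit <- vsprl:::fit_logistic(matrix(1, 75, 1), y)
  expect_equal(unname(fit$coefficients), qlogis(mean(y)), tolerance = 1e-6)
  expect_equal(fit$log_lik,
               sum(dbinom(y, 1, mean(y), log = TRUE)), tolerance = 1e-8)
})

test_that("pooled fits recover generative influence coefficients", {
  d <- add_predictors(default_design())
  truth <- c(cfb = 1.5, accfb = 0, oc = 1, b0 = 0)
  set.seed(52)
  pooled <- purrr::map_dfr(1:150, function(i) {
    eta <- truth["cfb"] * d$cfb + truth["accfb"] * d$accfb +
      truth["oc"] * d$oc + truth["b0"]
    d$decision <- rbinom(nrow(d), 1, plogis(eta))
    d
  })
  f <- fit_influence(pooled)
  expect_lt(abs(f$coefficients[["beta_cfb"]] - 1.5), 0.1)
  expect_lt(abs(f$coefficients[["beta_accfb"]] - 0), 0.1)
  expect_lt(abs(f$coefficients[["beta_oc"]] - 1), 0.1)
  expect_lt(abs(f$coefficients[["beta_0"]] - 0), 0.1)
  expect_true(f$converged)
  expect_s3_class(tidy(f), "tbl_df")
  expect_identical(nrow(tidy(f)), 4L)
  expect_true(glance(f)$log_lik < 0)
})

test_that("flipping all decisions negates every coefficient", {
  d <- add_predictors(default_design())
  set.seed(53)
  d$decision <- rbinom(75, 1, plogis(0.8 * d$cfb - 0.5 * d$accfb + 0.3))
  f1 <- fit_influence(d)
  d$decision <- 1 - d$decision
  f2 <- fit_influence(d)
  expect_equal(unname(f2$coefficients), -unname(f1$coefficients),
               tolerance = 1e-5)
})

test_that("likelihood at the MLE dominates the generative coefficients", {
  d <- add_predictors(default_design())
  set.seed(54)
  truth <- c(1.2, -0.4, 0.9, 0.1)
  X <- cbind(d$cfb, d$accfb, d$oc, 1)
  for (rep in 1:5) {
    d$decision <- rbinom(75, 1, plogis(drop(X %*% truth)))
    f <- fit_influence(d)
    expect_gte(f$log_lik + 1e-10, loglik_logistic(truth, X, d$decision))
  }
})

test_that("degenerate designs are reported as rank deficient", {
  neutral <- add_predictors(
    tibble::tibble(trial = 1:20, valence = "neutral", oc_level = 3L)
  )
  set.seed(55)
  neutral$decision <- rbinom(20, 1, 0.5)
  expect_warning(f <- fit_influence(neutral), "rank deficient")
  expect_true(f$rank_deficient)
  expect_true(any(is.na(f$coefficients)))
})

test_that("separation triggers a flagged penalized fallback", {
  d <- add_predictors(default_design())
  # decisions perfectly determined by current feedback sign
  d$decision <- as.integer(d$cfb >= 0)
  expect_warning(f <- fit_influence(d), "separation")
  expect_true(f$separated)
  expect_identical(f$method, "firth")
  expect_true(all(is.finite(f$coefficients)))
  expect_lt(abs(f$coefficients[["beta_cfb"]]), 15)
})

test_that("cohort fitting excludes flagged participants and keeps the rest", {
  d <- default_design()
  co <- simulate_cohort(cohort_spec(n_agents = 8, seed = 56), d)
  trials <- co$trials
  # overwrite two participants with uniform presses
  trials$decision[trials$participant == 1] <- 1L
  trials$decision[trials$participant == 2] <- 0L
  fits <- fit_influence_cohort(trials)
  expect_identical(nrow(fits), 8L)
  expect_identical(sum(fits$excluded), 2L)
  expect_true(all(is.na(fits$beta_cfb[fits$excluded])))
  expect_true(all(!is.na(fits$beta_cfb[!fits$excluded])))
  expect_error(fit_influence_cohort(trials[0, ]), "empty")
})

test_that("fitted cFB influence rises with the generative learning rate", {
  co <- small_cohort()
  merged <- dplyr::inner_join(co$glm_fits[!co$glm_fits$excluded, ],
                              co$participants, by = "participant")
  expect_gt(cor(merged$true_alpha, merged$beta_cfb, method = "spearman"), 0)
})
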
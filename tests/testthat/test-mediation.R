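test_that("grubbs screen removes exactly the planted extreme point", {
  v <- c(1.0, 1.1, 0.9, 1.05, 12.0)
  # frozen hand computation: G = (12 - mean)/sd, two-sided critical value at n = 5
  gs <- grubbs_screen(v)
  expect_equal(gs$g, 1.788652, tolerance = 1e-5)
  expect_equal(gs$g_crit, 1.715037, tolerance = 1e-5)
  expect_identical(gs$removed, 5L)
  expect_identical(gs$kept, v[-5])

  clean <- c(0.2, -0.1, 0.05, 0.3, -0.25, 0.1, 0.0)
  gs2 <- grubbs_screen(clean)
  expect_false(gs2$outlier_detected)
  expect_identical(gs2$kept, clean)

  expect_error(grubbs_screen(c(1, 2)), "n >= 3")
  expect_false(grubbs_screen(rep(1, 10))$outlier_detected)
})

test_that("grubbs screen is single-pass: at most one removal", {
  v <- c(rnorm(20), 10, -10)
  gs <- grubbs_screen(v)
  expect_lte(length(gs$removed), 1L)
  expect_gte(length(gs$kept), length(v) - 1L)
})

test_that("the OLS decomposition c = c' + a*b is exact", {
  set.seed(81)
  for (rep in 1:10) {
    d <- tibble::tibble(
      age = runif(30, 10, 25),
      mediator = rnorm(30, 2 * age, 3),
      outcome = rnorm(30, 0.5 * mediator - 0.2 * age, 2)
    )
    f <- bootstrap_mediation(d, n_boot = 50, seed = rep)
    expect_equal(f$c_hat, f$c_prime_hat + f$indirect, tolerance = 1e-12)
    # cross-check paths against lm
    expect_equal(f$a_hat, unname(coef(lm(mediator ~ age, d))[2]),
                 tolerance = 1e-10)
    expect_equal(f$b_hat,
                 unname(coef(lm(outcome ~ mediator + age, d))[2]),
                 tolerance = 1e-10)
    expect_equal(f$c_hat, unname(coef(lm(outcome ~ age, d))[2]),
                 tolerance = 1e-10)
  }
})

test_that("a near-noiseless generator pins the indirect effect", {
  # exactly zero mediator noise would make mediator and age collinear and
  # the b path unidentifiable; epsilon noise keeps the model well posed
  # (1e-4, comfortably above the cancellation error of the moment sums)

  spec <- mediation_cohort_spec(n = 40, a_path = 0.5, b_path = 0.4,
                                c_prime = 0.1, mediator_noise_sd = 1e-4,
                                outcome_noise_sd = 0, seed = 82)
  d <- simulate_mediation_cohort(spec)
  f <- bootstrap_mediation(d, n_boot = 300, seed = 83)
  expect_equal(f$indirect, 0.2, tolerance = 1e-4)
  expect_lt(f$ci[2] - f$ci[1], 1e-3)
})

test_that("bootstrap CIs are deterministic given data and seed", {
  d <- simulate_mediation_cohort(mediation_cohort_spec(seed = 84))
  f1 <- bootstrap_mediation(d, n_boot = 400, seed = 85)
  f2 <- bootstrap_mediation(d, n_boot = 400, seed = 85)
  expect_identical(f1$ci, f2$ci)
  f3 <- bootstrap_mediation(d, n_boot = 400, seed = 86)
  expect_false(identical(f1$ci, f3$ci))
  # bias-corrected variant runs and brackets sanely
  fb <- bootstrap_mediation(d, n_boot = 400, seed = 85,
                            ci_type = "bias_corrected")
  expect_lte(fb$ci[1], fb$ci[2])
})

test_that("input validation rejects unusable mediation data", {
  d <- simulate_mediation_cohort(mediation_cohort_spec(n = 20, seed = 87))
  d$mediator[3] <- NA
  expect_error(bootstrap_mediation(d, n_boot = 50, seed = 1), "missing")
  d2 <- simulate_mediation_cohort(mediation_cohort_spec(n = 20, seed = 87))
  d2$mediator <- d2$age   # collinear
  expect_error(bootstrap_mediation(d2, n_boot = 50, seed = 1),
               "collinear")
})

test_that("the suite screens outliers and reports per-mediator rows", {
  spec <- mediation_cohort_spec(n = 56, n_outliers = 1,
                                outlier_magnitude = 14, seed = 88)
  d <- simulate_mediation_cohort(spec)
  res <- run_mediation_suite(d, mediators = "mediator",
                             outcome = "outcome", n_boot = 400, seed = 89)
  expect_identical(nrow(res), 1L)
  expect_identical(res$outlier_removed, which(d$is_injected_outlier))
  expect_identical(res$n, 55L)

  # screened estimate is closer to truth than the contaminated one
  raw <- bootstrap_mediation(d, n_boot = 400, seed = 89)
  expect_lt(abs(res$indirect - 0.2), abs(raw$indirect - 0.2))

  # duplicated mediator column gives identical rows
  d$mediator2 <- d$mediator
  res2 <- run_mediation_suite(d, mediators = c("mediator", "mediator2"),
                              outcome = "outcome", n_boot = 200, seed = 90)
  expect_equal(res2$indirect[1], res2$indirect[2])
  expect_equal(res2$ci_lower[1], res2$ci_lower[2])

  # a mediator unrelated to age and outcome stays non-significant
  set.seed(91)
  d$noise <- rnorm(nrow(d))
  res3 <- run_mediation_suite(d, mediators = "noise", outcome = "outcome",
                              n_boot = 400, seed = 92)
  expect_false(res3$significant)
})
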
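test_that("age regression recovers exact linear trends", {
  d <- tibble::tibble(age = 10:25, y = 2 - 0.1 * (10:25))
  r <- suppressWarnings(regress_on_age(d, y))  # perfect fit
  expect_equal(r$estimate, -0.1, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
  expect_identical(r$df1, 1)
  expect_identical(r$df2, 14)
  expect_error(regress_on_age(d[1:2, ], y), "at least 3")
  expect_error(regress_on_age(dplyr::mutate(d, y = 1), y), "degenerate")
})

test_that("one-sample t matches the hand-computed statistic", {
  r <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  sym <- one_sample_t(c(-2, -1, 0, 1, 2), mu0 = 0)
  expect_equal(sym$statistic, 0)
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

test_that("wilcoxon signed rank agrees with the reference implementation", {
  # exact branch, n = 8, no ties
  x8 <- c(1.3, -0.4, 2.1, 0.7, -1.6, 0.9, 3.2, 0.2)
  mine <- wilcoxon_signed_rank(x8, mu0 = 0)
  ref <- wilcox.test(x8, mu = 0, exact = TRUE)
  expect_true(mine$exact)
  expect_equal(mine$V, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # exact p equals direct enumeration over all 2^8 sign patterns
  r <- rank(abs(x8))
  v_obs <- sum(r[x8 > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_all <- drop(signs %*% r)
  p_enum <- mean(abs(v_all - sum(r) / 2) >= abs(v_obs - sum(r) / 2))
  expect_equal(mine$p_value, p_enum, tolerance = 1e-12)

  # normal-approximation branch, n = 53
  set.seed(71)
  x53 <- rnorm(53, 0.3)
  mine53 <- wilcoxon_signed_rank(x53, mu0 = 0)
  ref53 <- wilcox.test(x53, mu = 0, exact = FALSE, correct = TRUE)
  expect_false(mine53$exact)
  expect_equal(mine53$p_value, ref53$p.value, tolerance = 1e-6)

  # symmetric data: z near zero
  sym <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3) + 10, mu0 = 10)
  expect_lt(abs(sym$statistic), 0.5)
  expect_error(wilcoxon_signed_rank(rep(5, 10), mu0 = 5), "nonzero")
})

test_that("spearman correlation uses mid-ranks and matches the definition", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlation(x, x^3)$estimate, 1)
  expect_equal(spearman_correlation(x, -x)$estimate, -1)
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_correlation(xt, yt)$estimate,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("the feedback-type by age interaction is the slope difference", {
  ages <- c(10, 20)
  d <- tibble::tibble(
    participant = rep(1:2, each = 2),
    age = rep(ages, 2),
    feedback_type = rep(c("cfb", "accfb"), each = 2),
    estimate = c(1 + 2 * ages, 0.5 + 5 * ages)
  )
  r <- suppressWarnings(ancova_interaction(d, estimate, feedback_type))
  expect_equal(abs(r$estimate), 3, tolerance = 1e-10)
  bad <- d[-1, ]
  expect_error(ancova_interaction(bad, estimate, feedback_type),
               "unbalanced")
})

test_that("bootstrap regression degenerates correctly", {
  d <- tibble::tibble(age = seq(10, 25, length.out = 20),
                      y = 3 - 0.2 * seq(10, 25, length.out = 20))
  r <- bootstrap_regression(d, y, n_boot = 200, seed = 72)
  expect_equal(r$estimate, -0.2, tolerance = 1e-10)
  expect_lt(r$ci_upper - r$ci_lower, 1e-10)
  expect_true(r$significant)

  const <- tibble::tibble(age = 1:10, y = 5)
  rc <- bootstrap_regression(const, y, n_boot = 100, seed = 73)
  expect_identical(rc$estimate, 0)
  expect_equal(c(rc$ci_lower, rc$ci_upper), c(0, 0))
  expect_error(bootstrap_regression(d, y, n_boot = 10), "seed")
})

test_that("shapiro wrapper enforces its range and flags skew", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  set.seed(74)
  skewed <- rexp(58)
  expect_lt(shapiro_wilk(skewed)$p_value, 0.05)
  r <- shapiro_wilk(rnorm(58))
  expect_true(r$statistic > 0 && r$statistic <= 1)
})

test_that("the cohort battery reproduces the developmental dissociation", {
  co <- small_cohort()
  res <- group_analysis(co$glm_fits, co$rl_fits, co$participants,
                        n_boot = 500, seed = 75)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  g <- function(a) res[res$analysis == a, ]
  expect_lt(g("cfb_on_age")$estimate, 0)
  # at this fixture scale the robust signature is the slope dissociation
  expect_gt(g("accfb_on_age")$estimate, g("cfb_on_age")$estimate)
  expect_lt(g("alpha_on_age_bootstrap")$estimate, 0)
  expect_gt(g("alpha_vs_cfb_influence")$estimate, 0)
  expect_lt(g("alpha_vs_accfb_influence")$estimate, 0)
  boot <- g("alpha_on_age_bootstrap")
  expect_lte(boot$ci_lower, boot$ci_upper)
})
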
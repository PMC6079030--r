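# All group-level tests are two-tailed and return a one-row tibble with a
# common column set so results can be row-bound into a single report.

group_result <- function(analysis, estimate = NA_real_, se = NA_real_,
                         statistic = NA_real_, df1 = NA_real_,
                         df2 = NA_real_, p_value = NA_real_,
                         ci_lower = NA_real_, ci_upper = NA_real_,
                         n = NA_integer_, method = NA_character_, ...) {
  tibble::tibble(
    analysis = analysis, estimate = estimate, se = se,
    statistic = statistic, df1 = df1, df2 = df2, p_value = p_value,
    ci_lower = ci_lower, ci_upper = ci_upper, n = as.integer(n),
    method = method, ...
  )
}

#' Linear regression of a participant-level estimate on age
#'
#' OLS of `value ~ age`; reports the slope, its standard error, and the
#' F-test for the age term (two-tailed).
#'
#' @param data A data frame of participant-level values.
#' @param value,age Columns (tidy-eval) holding the dependent variable and
#'   age.
#' @return A one-row tibble (analysis, estimate = slope, se, statistic = F,
#'   df1, df2, p_value, n).
#' @export
#' @examples
#' d <- tibble::tibble(age = 10:25, y = 2 - 0.1 * (10:25) + rnorm(16, 0, .1))
#' regress_on_age(d, y)
regress_on_age <- function(data, value, age = age) {
  y <- dplyr::pull(data, {{ value }})
  x <- dplyr::pull(data, {{ age }})
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate variance in regression input", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  group_result(
    analysis = "age_regression",
    estimate = unname(stats::coef(fit)[2]),
    se = sm$coefficients[2, 2],
    statistic = unname(fstat[1]), df1 = unname(fstat[2]),
    df2 = unname(fstat[3]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    n = length(x), method = "ols_f_test"
  )
}

# Vectorized OLS slopes for case-resampling bootstrap: idx is an n x B
# matrix of resampled row indices.
boot_slopes <- function(x, y, idx) {
  n <- nrow(idx)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  mx <- colMeans(xb); my <- colMeans(yb)
  sxy <- colSums(xb * yb) - n * mx * my
  sxx <- colSums(xb * xb) - n * mx * mx
  ifelse(sxx > 0, sxy / sxx, 0)
}

#' Nonparametric bootstrap regression of a value on age
#'
#' Case-resampling bootstrap of the OLS slope with a percentile confidence
#' interval; the effect is called significant when the interval excludes 0.
#' Used for learning-rate-on-age trajectories, whose residuals are
#' typically non-normal.
#'
#' @inheritParams regress_on_age
#' @param n_boot Number of bootstrap resamples. Default 5000.
#' @param conf_level Confidence level. Default 0.95.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A one-row tibble; `estimate` is the full-sample OLS slope,
#'   `ci_lower`/`ci_upper` the percentile interval, `se` the bootstrap SE.
#' @export
bootstrap_regression <- function(data, value, age = age, n_boot = 5000,
                                 conf_level = 0.95, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  y <- dplyr::pull(data, {{ value }})
  x <- dplyr::pull(data, {{ age }})
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  slope <- if (stats::var(x) > 0) stats::cov(x, y) / stats::var(x) else 0
  old <- globalenv()$.Random.seed
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sl <- boot_slopes(x, y, idx)
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(sl, c(a, 1 - a), type = 6))
  group_result(
    analysis = "bootstrap_age_regression",
    estimate = slope, se = stats::sd(sl),
    ci_lower = ci[1], ci_upper = ci[2],
    p_value = NA_real_, n = n, method = "percentile_bootstrap",
    n_boot = n_boot,
    significant = ci[1] > 0 | ci[2] < 0
  )
}

#' Feedback-type by age interaction (ANCOVA)
#'
#' Tests whether the age trajectories of the current-feedback and
#' accumulated-feedback influences diverge: a linear model
#' `estimate ~ feedback_type + age + feedback_type:age` with an F-test on
#' the interaction term. Every participant must contribute one row per
#' feedback type.
#'
#' @param data Long data frame.
#' @param estimate,feedback_type,age Columns (tidy-eval).
#' @return A one-row tibble; `estimate` is the interaction coefficient
#'   (difference in age slopes), `statistic` its F.
#' @export
ancova_interaction <- function(data, estimate, feedback_type, age = age) {
  y <- dplyr::pull(data, {{ estimate }})
  type <- as.factor(dplyr::pull(data, {{ feedback_type }}))
  x <- dplyr::pull(data, {{ age }})
  if (nlevels(type) != 2) {
    stop("feedback_type must have exactly two levels", call. = FALSE)
  }
  tab <- table(type)
  if (length(unique(tab)) != 1) {
    stop("unbalanced rows: every participant must contribute both ",
         "feedback-type rows", call. = FALSE)
  }
  fit <- stats::lm(y ~ type * x)
  an <- stats::anova(fit)
  irow <- which(rownames(an) == "type:x")
  group_result(
    analysis = "feedback_type_by_age_interaction",
    estimate = unname(stats::coef(fit)[4]),
    statistic = an$`F value`[irow],
    df1 = an$Df[irow], df2 = an$Df[nrow(an)],
    p_value = an$`Pr(>F)`[irow],
    n = length(y) / 2, method = "ancova_f_test"
  )
}

#' One-sample t test
#'
#' Standard two-tailed one-sample t test of a vector of participant-level
#' estimates against `mu0`.
#'
#' @param values Numeric vector.
#' @param mu0 Null value. Default 0.
#' @param conf_level Confidence level for the CI. Default 0.95.
#' @return A one-row tibble.
#' @export
one_sample_t <- function(values, mu0 = 0, conf_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0, conf.level = conf_level)
  group_result(
    analysis = "one_sample_t",
    estimate = unname(tt$estimate), se = unname(tt$stderr),
    statistic = unname(tt$statistic), df1 = unname(tt$parameter),
    p_value = tt$p.value,
    ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
    n = length(values), method = "t_test"
  )
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test against `mu0`. Exact-ties with `mu0` are
#' dropped (the signed-rank convention). For n <= 25 without ties among the
#' absolute differences the p-value is computed from the exact signed-rank
#' distribution; otherwise the normal approximation with continuity and
#' tie corrections is used. The z statistic (signed, from the normal
#' approximation) is always reported, along with the median and
#' interquartile range of the input as descriptives.
#'
#' @param values Numeric vector.
#' @param mu0 Null location.
#' @return A one-row tibble; `statistic` is z, with extra columns `V`
#'   (positive-rank sum), `median`, `iqr`, and `exact`.
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need at least 5 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  has_ties <- any(ties > 1)
  mu_v <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- sign(V - mu_v) * 0.5
  z <- (V - mu_v - cc) / sqrt(sigma2)
  exact <- n <= 25 && !has_ties
  p <- if (exact) {
    if (V > mu_v) {
      min(1, 2 * stats::psignrank(V - 1, n, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::psignrank(V, n))
    }
  } else {
    2 * stats::pnorm(-abs(z))
  }
  group_result(
    analysis = "wilcoxon_signed_rank",
    estimate = stats::median(values), statistic = z, p_value = p,
    n = n, method = if (exact) "exact" else "normal_approximation",
    V = V, median = stats::median(values),
    iqr = stats::IQR(values), exact = exact
  )
}

#' Spearman rank-order correlation
#'
#' Rank correlation with mid-ranks for ties; two-tailed p-value.
#'
#' @param x,y Numeric vectors.
#' @return A one-row tibble; `estimate` is rho.
#' @export
spearman_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  group_result(
    analysis = "spearman_correlation",
    estimate = unname(ct$estimate), statistic = unname(ct$statistic),
    p_value = ct$p.value, n = length(x), method = "spearman"
  )
}

#' Shapiro-Wilk normality test
#'
#' Used to route group analyses to nonparametric branches when residuals
#' are non-normal.
#'
#' @param residuals Numeric vector, 3 <= n <= 5000.
#' @return A one-row tibble; `statistic` is W.
#' @export
shapiro_wilk <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 3 || length(residuals) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(residuals)
  group_result(
    analysis = "shapiro_wilk",
    statistic = unname(sw$statistic), p_value = sw$p.value,
    n = length(residuals), method = "shapiro_wilk"
  )
}

#' Group-level analysis of a fitted cohort
#'
#' Convenience wrapper reproducing the standard battery on a cohort's fits:
#' age regressions of the current- and accumulated-feedback influences,
#' their feedback-type x age interaction, a bootstrap age regression of the
#' learning rate (with a Shapiro-Wilk routing check), and the Spearman
#' correlations between the learning rate and the two influence estimates.
#' Violators and excluded participants are dropped.
#'
#' @param glm_fits Output of [fit_influence_cohort()].
#' @param rl_fits Output of [fit_rl_cohort()].
#' @param participants Participant table with `participant` and `age`.
#' @param n_boot Bootstrap resamples for the learning-rate regression.
#' @param seed Integer seed.
#' @return A tibble of group results, one row per analysis.
#' @export
group_analysis <- function(glm_fits, rl_fits, participants,
                           n_boot = 5000, seed = 1L) {
  g <- dplyr::inner_join(
    glm_fits[!glm_fits$excluded, ],
    participants[, c("participant", "age")], by = "participant"
  )
  r <- dplyr::inner_join(
    rl_fits[!rl_fits$excluded & !rl_fits$violator, ],
    participants[, c("participant", "age")], by = "participant"
  )
  long <- tidyr::pivot_longer(
    g[, c("participant", "age", "beta_cfb", "beta_accfb")],
    cols = c("beta_cfb", "beta_accfb"),
    names_to = "feedback_type", values_to = "estimate"
  )
  both <- dplyr::inner_join(
    g[, c("participant", "beta_cfb", "beta_accfb")],
    r[, c("participant", "alpha_hat")], by = "participant"
  )
  dplyr::bind_rows(
    dplyr::mutate(regress_on_age(g, beta_cfb), analysis = "cfb_on_age"),
    dplyr::mutate(regress_on_age(g, beta_accfb), analysis = "accfb_on_age"),
    dplyr::mutate(
      ancova_interaction(long, estimate, feedback_type),
      analysis = "feedback_type_by_age_interaction"
    ),
    dplyr::mutate(shapiro_wilk(stats::residuals(
      stats::lm(alpha_hat ~ age, data = r)
    )), analysis = "alpha_residual_normality"),
    dplyr::mutate(
      bootstrap_regression(r, alpha_hat, n_boot = n_boot, seed = seed),
      analysis = "alpha_on_age_bootstrap"
    ),
    dplyr::mutate(
      spearman_correlation(both$alpha_hat, both$beta_cfb),
      analysis = "alpha_vs_cfb_influence"
    ),
    dplyr::mutate(
      spearman_correlation(both$alpha_hat, both$beta_accfb),
      analysis = "alpha_vs_accfb_influence"
    )
  )
}
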
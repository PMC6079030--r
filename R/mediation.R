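#' Grubbs single-outlier screen
#'
#' Two-sided Grubbs test on the maximum absolute studentized deviation
#' `G = max |x - mean(x)| / sd(x)`. At most one point (the most deviant)
#' is removed, and only when G exceeds the critical value at
#' `alpha_level`; the test is single-pass, mirroring single-extreme-outlier
#' screening of ROI estimates before mediation.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha_level Significance level. Default 0.05.
#' @return A list: `kept` (values with the outlier removed, if any),
#'   `removed` (index into `values`, or `integer(0)`), `g` (the statistic),
#'   `g_crit` (the critical value), `outlier_detected`.
#' @export
#' @examples
#' grubbs_screen(c(1.0, 1.1, 0.9, 1.05, 12.0))$removed
grubbs_screen <- function(values, alpha_level = 0.05) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 3) stop("Grubbs test requires n >= 3", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(kept = values, removed = integer(0), g = 0,
                g_crit = NA_real_, outlier_detected = FALSE))
  }
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  g <- dev[i] / s
  tq <- stats::qt(alpha_level / (2 * n), df = n - 2, lower.tail = FALSE)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  if (g > g_crit) {
    list(kept = values[-i], removed = i, g = g, g_crit = g_crit,
         outlier_detected = TRUE)
  } else {
    list(kept = values, removed = integer(0), g = g, g_crit = g_crit,
         outlier_detected = FALSE)
  }
}

# Closed-form mediation paths for y ~ m + x and m ~ x (single mediator).
# Returns a (x->m), b (m->y | x), c (total), c_prime = c - a*b.
mediation_paths <- function(x, m, y) {
  n <- length(x)
  sxx <- sum(x * x) - n * mean(x)^2
  smm <- sum(m * m) - n * mean(m)^2
  sxm <- sum(x * m) - n * mean(x) * mean(m)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  smy <- sum(m * y) - n * mean(m) * mean(y)
  det <- smm * sxx - sxm^2
  if (sxx <= 0 || det <= 0) return(NULL)
  a <- sxm / sxx
  b <- (smy * sxx - sxy * sxm) / det
  cc <- sxy / sxx
  c(a = a, b = b, c = cc, c_prime = cc - a * b)
}

#' Bootstrap mediation of an age effect through a mediator
#'
#' Simple-mediation model estimated by two OLS fits
#' (`mediator ~ age` for the a path; `outcome ~ mediator + age` for the
#' b and direct paths), with the indirect effect `a * b` inferred by
#' case-resampling bootstrap. The total effect decomposes exactly as
#' `c = c' + a * b`. Significance is claimed when the bootstrap CI for the
#' indirect effect excludes 0.
#'
#' @param data Data frame of participant-level values.
#' @param age,mediator,outcome Columns (tidy-eval).
#' @param n_boot Bootstrap resamples. Default 5000.
#' @param conf_level Confidence level. Default 0.95.
#' @param seed Integer seed (required).
#' @param ci_type `"percentile"` (default) or `"bias_corrected"`.
#' @param standardize Z-score all three variables first. Default FALSE.
#' @return An object of class `mediation_fit` with paths `a_hat`, `b_hat`,
#'   `c_hat`, `c_prime_hat`, `indirect`, bootstrap `se_boot` and `ci`,
#'   `significant`, `n`, `n_boot`.
#' @export
bootstrap_mediation <- function(data, age = age, mediator = mediator,
                                outcome = outcome, n_boot = 5000,
                                conf_level = 0.95, seed,
                                ci_type = c("percentile", "bias_corrected"),
                                standardize = FALSE) {
  ci_type <- match.arg(ci_type)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  x <- dplyr::pull(data, {{ age }})
  m <- dplyr::pull(data, {{ mediator }})
  y <- dplyr::pull(data, {{ outcome }})
  if (anyNA(x) || anyNA(m) || anyNA(y)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  n <- length(x)
  if (n < 10) stop("need n >= 10", call. = FALSE)
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m))
    y <- as.numeric(scale(y))
  }
  paths <- mediation_paths(x, m, y)
  if (is.null(paths)) {
    stop("zero variance or collinear age/mediator", call. = FALSE)
  }
  indirect <- unname(paths["a"] * paths["b"])

  old <- globalenv()$.Random.seed
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  xb <- matrix(x[idx], nrow = n)
  mb <- matrix(m[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  mxb <- colMeans(xb); mmb <- colMeans(mb); myb <- colMeans(yb)
  sxx <- colSums(xb * xb) - n * mxb^2
  smm <- colSums(mb * mb) - n * mmb^2
  sxm <- colSums(xb * mb) - n * mxb * mmb
  sxy <- colSums(xb * yb) - n * mxb * myb
  smy <- colSums(mb * yb) - n * mmb * myb
  det <- smm * sxx - sxm^2
  ok <- sxx > 0 & det > 0
  ab <- (sxm[ok] / sxx[ok]) *
    ((smy[ok] * sxx[ok] - sxy[ok] * sxm[ok]) / det[ok])
  alpha2 <- (1 - conf_level) / 2
  if (ci_type == "percentile") {
    ci <- unname(stats::quantile(ab, c(alpha2, 1 - alpha2), type = 6))
  } else {
    z0 <- stats::qnorm(mean(ab < indirect))
    lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha2))
    hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha2))
    ci <- unname(stats::quantile(ab, c(lo_p, hi_p), type = 6))
  }
  structure(
    list(
      a_hat = unname(paths["a"]), b_hat = unname(paths["b"]),
      c_hat = unname(paths["c"]), c_prime_hat = unname(paths["c_prime"]),
      indirect = indirect, se_boot = stats::sd(ab),
      ci = ci, conf_level = conf_level, ci_type = ci_type,
      significant = ci[1] > 0 || ci[2] < 0,
      n = n, n_boot = n_boot, n_boot_ok = sum(ok)
    ),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> n = ", x$n, ", ", x$n_boot, " bootstrap samples\n",
      "  a = ", signif(x$a_hat, 3), ", b = ", signif(x$b_hat, 3),
      ", c' = ", signif(x$c_prime_hat, 3), "\n",
      "  indirect a*b = ", signif(x$indirect, 3),
      " (SE ", signif(x$se_boot, 3), "), ",
      round(100 * x$conf_level), "% CI [",
      signif(x$ci[1], 3), ", ", signif(x$ci[2], 3), "]",
      if (x$significant) " *", "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy mediation_fit
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(x$a_hat, x$b_hat, x$c_hat, x$c_prime_hat, x$indirect)
  )
}

#' @export
#' @method glance mediation_fit
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    indirect = x$indirect, se_boot = x$se_boot,
    ci_lower = x$ci[1], ci_upper = x$ci[2],
    significant = x$significant, n = x$n, n_boot = x$n_boot
  )
}

#' Run a suite of mediation analyses over one or more mediator columns
#'
#' For each mediator: Grubbs screening of the mediator values (dropping at
#' most one extreme case), a prerequisite age-mediator correlation check,
#' then bootstrap mediation on the screened rows.
#'
#' @param data Participant-level data frame.
#' @param mediators Character vector of mediator column names.
#' @param outcome Outcome column name.
#' @param age Age column name. Default `"age"`.
#' @param n_boot,conf_level,seed,ci_type Passed to [bootstrap_mediation()].
#' @param grubbs_alpha Level of the outlier screen.
#' @return A tibble with one row per mediator: paths, indirect effect,
#'   bootstrap CI, significance, outlier index (`NA` when none), and the
#'   age-mediator correlation `r_age_mediator` with its p-value.
#' @export
run_mediation_suite <- function(data, mediators, outcome, age = "age",
                                n_boot = 5000, conf_level = 0.95, seed = 1L,
                                ci_type = "percentile",
                                grubbs_alpha = 0.05) {
  stopifnot(all(c(mediators, outcome, age) %in% names(data)))
  purrr::map_dfr(mediators, function(mcol) {
    gs <- grubbs_screen(data[[mcol]], alpha_level = grubbs_alpha)
    d <- if (gs$outlier_detected) data[-gs$removed, ] else data
    prereq <- stats::cor.test(d[[age]], d[[mcol]])
    fit <- bootstrap_mediation(
      d, age = !!rlang::sym(age), mediator = !!rlang::sym(mcol),
      outcome = !!rlang::sym(outcome),
      n_boot = n_boot, conf_level = conf_level, seed = seed,
      ci_type = ci_type
    )
    tibble::tibble(
      mediator = mcol, outcome = outcome,
      a_hat = fit$a_hat, b_hat = fit$b_hat, c_hat = fit$c_hat,
      c_prime_hat = fit$c_prime_hat, indirect = fit$indirect,
      se_boot = fit$se_boot, ci_lower = fit$ci[1], ci_upper = fit$ci[2],
      significant = fit$significant, n = fit$n, n_boot = fit$n_boot,
      outlier_removed = if (gs$outlier_detected) gs$removed else NA_integer_,
      r_age_mediator = unname(prereq$estimate),
      p_age_mediator = prereq$p.value
    )
  })
}
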
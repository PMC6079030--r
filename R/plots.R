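#' Plot age trajectories of fitted influence and learning-rate estimates
#'
#' Scatter of per-participant estimates against age with OLS trend lines,
#' faceted by estimate. The expected developmental pattern on the default
#' synthetic cohort is a falling current-feedback influence and learning
#' rate and a rising accumulated-feedback influence.
#'
#' @param glm_fits Output of [fit_influence_cohort()].
#' @param rl_fits Output of [fit_rl_cohort()].
#' @param participants Participant table with `participant` and `age`.
#' @return A ggplot object.
#' @export
plot_age_trajectories <- function(glm_fits, rl_fits, participants) {
  g <- dplyr::inner_join(glm_fits[!glm_fits$excluded, ],
                         participants[, c("participant", "age")],
                         by = "participant")
  r <- dplyr::inner_join(
    rl_fits[!rl_fits$excluded & !rl_fits$violator, ],
    participants[, c("participant", "age")], by = "participant"
  )
  long <- dplyr::bind_rows(
    tibble::tibble(age = g$age, estimate = g$beta_cfb,
                   term = "cFB influence"),
    tibble::tibble(age = g$age, estimate = g$beta_accfb,
                   term = "accFB influence"),
    tibble::tibble(age = r$age, estimate = r$alpha_hat,
                   term = "learning rate")
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$age, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "purple") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "estimate") +
    ggplot2::theme_minimal()
}

#' Plot the VSP-conditioned partner-evaluation bias
#'
#' Per-participant mean decision probabilities in high- and low-VSP trial
#' sets against the chance level of 0.5.
#'
#' @param bias A `vsp_bias` object from [vsp_bias_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_vsp_bias <- function(bias, ...) {
  stopifnot(inherits(bias, "vsp_bias"))
  long <- tidyr::pivot_longer(
    bias$per_participant[, c("participant", "mean_p_high", "mean_p_low")],
    cols = c("mean_p_high", "mean_p_low"),
    names_to = "set", values_to = "p"
  )
  long$set <- ifelse(long$set == "mean_p_high", "VSP > 0", "VSP < 0")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data$p)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "mean P(rate partner creative)",
                  title = "Partner-evaluation bias by VSP state") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot vsp_bias
autoplot.vsp_bias <- function(object, ...) plot_vsp_bias(object, ...)

#' Plot a mediation path diagram summary
#'
#' Simple annotated diagram of the age -> mediator -> outcome paths with
#' the bootstrap CI of the indirect effect.
#'
#' @param object A `mediation_fit` from [bootstrap_mediation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot mediation_fit
autoplot.mediation_fit <- function(object, ...) {
  nodes <- tibble::tibble(
    x = c(0, 1, 2), y = c(0, 1, 0),
    label = c("age", "mediator", "outcome")
  )
  edges <- tibble::tibble(
    x = c(0.1, 1.1, 0.1), y = c(0.1, 0.9, 0),
    xend = c(0.9, 1.9, 1.9), yend = c(0.9, 0.1, 0),
    label = c(sprintf("a = %.3g", object$a_hat),
              sprintf("b = %.3g", object$b_hat),
              sprintf("c' = %.3g", object$c_prime_hat))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches"))
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 5
    ) +
    ggplot2::geom_text(
      data = edges,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2 + 0.08,
                   label = .data$label)
    ) +
    ggplot2::annotate(
      "text", x = 1, y = -0.35,
      label = sprintf("indirect a*b = %.3g, %d%% CI [%.3g, %.3g]%s",
                      object$indirect, round(100 * object$conf_level),
                      object$ci[1], object$ci[2],
                      if (object$significant) " *" else "")
    ) +
    ggplot2::xlim(-0.3, 2.3) + ggplot2::ylim(-0.5, 1.3) +
    ggplot2::theme_void()
}
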
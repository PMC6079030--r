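#' Reverse-code feedback for the self-protection value update
#'
#' The value of self-protection (VSP) rises when evaluation turns negative,
#' so feedback enters the delta rule reverse-coded:
#' negative -> +1, neutral -> 0, positive -> -1.
#'
#' @param valence Character vector of valences.
#' @return Numeric vector in \{+1, 0, -1\}.
#' @export
reverse_code_fb <- function(valence) {
  -code_cfb(valence)
}

#' Delta-rule update of the value of self-protection
#'
#' Runs the Rescorla-Wagner recursion
#' `VSP_t = VSP_{t-1} + alpha * (FB_t - VSP_{t-1})` with `VSP_0 = 0`,
#' where `FB_t` is the reverse-coded feedback of trial t and
#' `FB_t - VSP_{t-1}` is the prediction error (PE).
#'
#' @param fb Numeric vector of reverse-coded feedback values, one per trial.
#' @param alpha Learning rate in [0, 1].
#' @return An object of class `vsp_trajectory`: a list with `vsp`
#'   (length T+1, including VSP_0 = 0), `pe` (length T), `fb`, and `alpha`.
#' @export
#' @examples
#' tr <- update_vsp(c(1, 1, 0, -1), alpha = 0.5)
#' tr$vsp
update_vsp <- function(fb, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  n <- length(fb)
  vsp <- numeric(n + 1L)
  pe <- numeric(n)
  for (t in seq_len(n)) {
    pe[t] <- fb[t] - vsp[t]
    vsp[t + 1L] <- vsp[t] + alpha * pe[t]
  }
  structure(list(vsp = vsp, pe = pe, fb = fb, alpha = alpha),
            class = "vsp_trajectory")
}

#' Closed-form value of the self-protection trajectory
#'
#' Direct evaluation of the unrolled delta rule,
#' `VSP_t = (1 - alpha)^t VSP_0 + sum_{i=1}^t (1 - alpha)^{t-i} alpha FB_i`
#' with `VSP_0 = 0`: an exponentially recency-weighted sum of all feedback,
#' with weights summing to at most 1.
#'
#' @inheritParams update_vsp
#' @param t Trial index (0 returns the initial value 0).
#' @return The value of VSP at trial `t`.
#' @export
closed_form_vsp <- function(fb, alpha, t) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(t >= 0, t <= length(fb))
  if (t == 0L) return(0)
  i <- seq_len(t)
  sum((1 - alpha)^(t - i) * alpha * fb[i])
}

#' @export
print.vsp_trajectory <- function(x, ...) {
  cat("<vsp_trajectory> ", length(x$pe), " trials, alpha = ", x$alpha,
      ", final VSP = ", signif(x$vsp[length(x$vsp)], 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method autoplot vsp_trajectory
#' @rdname plot_vsp_trajectory
autoplot.vsp_trajectory <- function(object, ...) {
  plot_vsp_trajectory(object, ...)
}

#' Plot a self-protection value trajectory
#'
#' Step plot of VSP over trials with the reverse-coded feedback overlaid.
#'
#' @param object A `vsp_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_vsp_trajectory <- function(object, ...) {
  d <- tibble::tibble(
    trial = seq_along(object$vsp) - 1L,
    vsp = object$vsp
  )
  fbd <- tibble::tibble(trial = seq_along(object$fb), fb = object$fb)
  ggplot2::ggplot(d, ggplot2::aes(x = trial, y = vsp)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = fbd, ggplot2::aes(y = fb),
      shape = 3, colour = "firebrick", alpha = 0.6
    ) +
    ggplot2::labs(
      x = "trial",
      y = "value of self-protection",
      title = sprintf("VSP trajectory (alpha = %.3g)", object$alpha),
      subtitle = "crosses: reverse-coded feedback"
    ) +
    ggplot2::theme_minimal()
}
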
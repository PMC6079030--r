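#' Code current feedback (cFB)
#'
#' Maps feedback valence to the current-feedback predictor:
#' negative -> -1, neutral -> 0, positive -> +1.
#'
#' @param valence Character vector of valences.
#' @return Numeric vector in \{-1, 0, +1\}.
#' @export
#' @examples
#' code_cfb(c("negative", "neutral", "positive"))
code_cfb <- function(valence) {
  map <- c(negative = -1, neutral = 0, positive = 1)
  out <- unname(map[valence])
  if (anyNA(out)) {
    stop("unknown valence: ",
         paste(unique(valence[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Compute the accumulated-feedback (accFB) predictor
#'
#' accFB at trial t is the sum of the feedback codes of trials 1..t-1,
#' rescaled by the design's running-sum bound so that it lies in [-1, +1]
#' for any conforming design. accFB of the first trial is 0.
#'
#' @param valence Character vector of valences, in trial order.
#' @param bound Rescaling divisor (the design's running-sum bound).
#' @return Numeric vector of per-trial accFB values.
#' @export
#' @examples
#' compute_accfb(c("positive", "negative", "positive", "neutral"))
compute_accfb <- function(valence, bound = 3) {
  stopifnot(length(valence) >= 1, bound >= 1)
  cfb <- code_cfb(valence)
  raw <- c(0, cumsum(cfb)[-length(cfb)])
  if (any(abs(raw) > bound)) {
    warning("running feedback sum exceeds the bound of ", bound,
            "; rescaled accFB leaves [-1, 1] (non-conforming design)",
            call. = FALSE)
  }
  raw / bound
}

#' Rescale objective creativity (OC) to [-1, +1]
#'
#' Linear map of the 1..5 creativity level: `(oc_level - 3) / 2`.
#'
#' @param oc_level Integer vector of creativity levels in 1..5.
#' @return Numeric vector in [-1, +1].
#' @export
rescale_oc <- function(oc_level) {
  if (any(!oc_level %in% 1:5)) {
    stop("oc_level must be an integer in 1..5", call. = FALSE)
  }
  (oc_level - 3) / 2
}

#' Build the trial-wise predictor table
#'
#' Adds the three decision-model regressors (`cfb`, `accfb`, `oc`) to a
#' trial table, computed per participant in trial order. Predictors are
#' used on their raw codings (no mean-centering).
#'
#' @param trials A data frame with columns `trial`, `valence`, `oc_level`
#'   and optionally `participant` (single-participant tables may omit it)
#'   and `decision`.
#' @param accfb_bound Rescaling bound for accFB. Default 3.
#' @return A tibble: the input columns plus `cfb`, `accfb`, `oc`.
#' @export
#' @examples
#' design <- generate_design(design_spec(seed = 1))
#' add_predictors(design)
add_predictors <- function(trials, accfb_bound = 3) {
  stopifnot(all(c("trial", "valence", "oc_level") %in% names(trials)))
  trials <- tibble::as_tibble(as.data.frame(trials))
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  check_one <- function(d) {
    if (anyDuplicated(d$trial)) {
      stop("duplicate trial index for participant ", d$participant[1],
           call. = FALSE)
    }
    if (!identical(as.integer(sort(d$trial)), seq_len(nrow(d)))) {
      stop("missing trial index for participant ", d$participant[1],
           call. = FALSE)
    }
  }
  out <- trials |>
    dplyr::group_by(participant) |>
    dplyr::group_modify(function(d, key) {
      d$participant <- key$participant
      check_one(d)
      d <- d[order(d$trial), ]
      d$cfb <- code_cfb(d$valence)
      d$accfb <- compute_accfb(d$valence, bound = accfb_bound)
      d$oc <- rescale_oc(d$oc_level)
      d$participant <- NULL
      d
    }) |>
    dplyr::ungroup()
  out
}
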
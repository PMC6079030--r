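#' Specify a reciprocal-evaluation task design
#'
#' A design crosses three feedback valences with five objective-creativity
#' (OC) levels, `n_per_cell` trials per cell (75 trials by default). The
#' presentation order is constrained: no more than `max_run_length`
#' consecutive trials of the same (valence, OC) condition, and the running
#' sum of valence codes (+1 positive, 0 neutral, -1 negative) must stay
#' within `[-accfb_bound, +accfb_bound]` at every trial, which keeps the
#' rescaled accumulated-feedback predictor inside `[-1, 1]`.
#'
#' @param n_per_cell Trials per (valence, OC) cell. Default 5.
#' @param valences Ordered character vector of feedback valences.
#' @param oc_levels Integer vector of objective-creativity levels.
#' @param max_run_length Longest permitted run of one condition. Default 2.
#' @param accfb_bound Bound on the running valence sum. Default 3.
#' @param seed Integer seed used by [generate_design()].
#' @param sequence_file Optional path to a CSV holding an explicit published
#'   trial sequence (columns `trial`, `valence`, `oc_level`, and optionally
#'   `neutral_subtype`); when set, [generate_design()] loads it instead of
#'   constructing one.
#'
#' @return An object of class `design_spec` (a named list).
#' @export
#' @examples
#' spec <- design_spec(seed = 1)
#' design <- generate_design(spec)
#' dplyr::count(design, valence)
design_spec <- function(n_per_cell = 5,
                        valences = c("negative", "neutral", "positive"),
                        oc_levels = 1:5,
                        max_run_length = 2,
                        accfb_bound = 3,
                        seed = 1L,
                        sequence_file = NULL) {
  stopifnot(
    n_per_cell >= 1, max_run_length >= 1, accfb_bound >= 1,
    length(valences) >= 1, length(oc_levels) >= 1,
    !anyDuplicated(valences), !anyDuplicated(oc_levels)
  )
  if (!all(valences %in% c("negative", "neutral", "positive"))) {
    stop("valences must be drawn from 'negative', 'neutral', 'positive'",
         call. = FALSE)
  }
  structure(
    list(
      n_per_cell = as.integer(n_per_cell),
      valences = valences,
      oc_levels = as.integer(oc_levels),
      max_run_length = as.integer(max_run_length),
      accfb_bound = as.integer(accfb_bound),
      seed = as.integer(seed),
      sequence_file = sequence_file
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ",
      x$n_per_cell, " per cell, ",
      length(x$valences), " valences x ", length(x$oc_levels), " OC levels (",
      x$n_per_cell * length(x$valences) * length(x$oc_levels), " trials), ",
      "max run ", x$max_run_length, ", |running sum| <= ", x$accfb_bound,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

valence_code <- function(valence) {
  unname(c(negative = -1L, neutral = 0L, positive = 1L)[valence])
}

#' Generate a constrained pseudorandom task design
#'
#' Builds a trial sequence by randomized sequential construction: at each
#' position a remaining condition instance is drawn uniformly among those
#' that neither extend a run beyond `max_run_length` nor push the running
#' valence sum outside `accfb_bound` (nor strand it where the remaining
#' trials could not return it to zero). Dead ends trigger a restart; an
#' error is raised after `max_restarts` failed attempts, which signals a
#' contradictory specification rather than bad luck.
#'
#' Neutral trials are split into the task's two cover-story subtypes
#' ("not_yet_evaluated" / "no_response") in a 4:1 ratio; the subtypes are
#' analytically identical and carried only for completeness.
#'
#' @param spec A [design_spec()].
#' @param max_restarts Restart budget for the constructive search.
#' @return A tibble of class `task_design` with columns `trial`, `valence`,
#'   `oc_level`, `neutral_subtype`.
#' @export
generate_design <- function(spec = design_spec(), max_restarts = 10000L) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(spec$sequence_file)) {
    return(read_design(spec$sequence_file))
  }
  cells <- tidyr::expand_grid(
    valence = spec$valences,
    oc_level = spec$oc_levels
  )
  pool0 <- cells[rep(seq_len(nrow(cells)), each = spec$n_per_cell), ]
  n_trials <- nrow(pool0)
  codes0 <- valence_code(pool0$valence)

  withr_seed <- spec$seed
  old <- globalenv()$.Random.seed
  set.seed(withr_seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  for (attempt in seq_len(max_restarts)) {
    remaining <- rep(TRUE, n_trials)
    order_idx <- integer(n_trials)
    run_len <- 0L
    last_cell <- NA_integer_
    s <- 0L
    # remaining positive / negative counts, for the can-return-to-bound check
    n_pos <- sum(codes0 == 1L)
    n_neg <- sum(codes0 == -1L)
    ok <- TRUE
    cell_id <- (match(pool0$valence, spec$valences) - 1L) *
      length(spec$oc_levels) + match(pool0$oc_level, spec$oc_levels)
    for (t in seq_len(n_trials)) {
      cand <- which(remaining)
      code_c <- codes0[cand]
      s_new <- s + code_c
      rem_pos <- n_pos - (code_c == 1L)
      rem_neg <- n_neg - (code_c == -1L)
      feasible <- abs(s_new) <= spec$accfb_bound &
        (s_new <= rem_neg) & (-s_new <= rem_pos)
      if (!is.na(last_cell) && run_len >= spec$max_run_length) {
        feasible <- feasible & cell_id[cand] != last_cell
      }
      cand <- cand[feasible]
      if (length(cand) == 0L) {
        ok <- FALSE
        break
      }
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      order_idx[t] <- pick
      remaining[pick] <- FALSE
      s <- s + codes0[pick]
      n_pos <- n_pos - (codes0[pick] == 1L)
      n_neg <- n_neg - (codes0[pick] == -1L)
      if (!is.na(last_cell) && cell_id[pick] == last_cell) {
        run_len <- run_len + 1L
      } else {
        run_len <- 1L
      }
      last_cell <- cell_id[pick]
    }
    if (ok) {
      design <- pool0[order_idx, ]
      design$trial <- seq_len(n_trials)
      design$neutral_subtype <- "none"
      neutral_idx <- which(design$valence == "neutral")
      if (length(neutral_idx) > 0L) {
        n_nye <- round(length(neutral_idx) * 4 / 5)
        nye <- sample(neutral_idx, n_nye)
        design$neutral_subtype[neutral_idx] <- "no_response"
        design$neutral_subtype[nye] <- "not_yet_evaluated"
      }
      out <- tibble::as_tibble(
        design[, c("trial", "valence", "oc_level", "neutral_subtype")]
      )
      class(out) <- c("task_design", class(out))
      return(out)
    }
  }
  stop("no valid trial sequence found within ", max_restarts,
       " restarts; the design constraints appear infeasible", call. = FALSE)
}

#' Validate a task design against its specification
#'
#' Checks cell counts, the run-length constraint, and the running-sum bound.
#' Never raises: returns a character vector of violation descriptions
#' (empty when the design conforms), each naming the trial index and rule.
#'
#' @param design A `task_design` tibble (or any data frame with columns
#'   `trial`, `valence`, `oc_level`).
#' @param spec The [design_spec()] to validate against.
#' @return Character vector of violations; `character(0)` if none.
#' @export
validate_design <- function(design, spec = design_spec()) {
  v <- character(0)
  design <- design[order(design$trial), ]
  counts <- dplyr::count(as.data.frame(design), valence, oc_level)
  full <- tidyr::expand_grid(valence = spec$valences,
                             oc_level = spec$oc_levels)
  full <- dplyr::left_join(full, counts, by = c("valence", "oc_level"))
  full$n[is.na(full$n)] <- 0L
  bad <- full[full$n != spec$n_per_cell, ]
  if (nrow(bad) > 0L) {
    v <- c(v, sprintf(
      "cell_count: (%s, OC %d) has %d trials, expected %d",
      bad$valence, bad$oc_level, bad$n, spec$n_per_cell
    ))
  }
  cond <- paste(design$valence, design$oc_level)
  run <- rle(cond)
  if (any(run$lengths > spec$max_run_length)) {
    ends <- cumsum(run$lengths)
    long <- which(run$lengths > spec$max_run_length)
    v <- c(v, sprintf(
      "max_run_length: run of %d identical conditions ending at trial %d",
      run$lengths[long], design$trial[ends[long]]
    ))
  }
  sums <- cumsum(valence_code(design$valence))
  over <- which(abs(sums) > spec$accfb_bound)
  if (length(over) > 0L) {
    v <- c(v, sprintf(
      "accfb_bound: running valence sum %d at trial %d exceeds +/-%d",
      sums[over], design$trial[over], spec$accfb_bound
    ))
  }
  v
}

#' Write or read a task design as CSV
#'
#' Plain CSV interchange with columns `trial`, `valence`, `oc_level`,
#' `neutral_subtype`; trial indices are 1-based.
#'
#' @param design A `task_design` tibble.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` a
#'   `task_design` tibble.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "valence", "oc_level")
  if (!all(need %in% names(df))) {
    stop("design file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$neutral_subtype)) df$neutral_subtype <- "none"
  out <- tibble::as_tibble(df[order(df$trial),
                              c("trial", "valence", "oc_level",
                                "neutral_subtype")])
  class(out) <- c("task_design", class(out))
  out
}
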
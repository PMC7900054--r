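#' Construct a 2x2 trial
#'
#' A single randomised comparison of an intervention against a control,
#' summarised as event counts and arm sizes. This is the atomic unit of
#' every analysis in the package: a cross-tabulation of arm
#' (intervention/control) by outcome (event/non-event).
#'
#' @param trial_id Character label identifying the trial.
#' @param events_t Integer, number of events in the intervention arm.
#' @param size_t Integer, number randomised to the intervention arm.
#' @param events_c Integer, number of events in the control arm.
#' @param size_c Integer, number randomised to the control arm.
#'
#' @return An object of class `two_by_two_trial`: a list with the five
#'   fields above plus `total_n = size_t + size_c`.
#'
#' @examples
#' two_by_two_trial("A", events_t = 1, size_t = 100, events_c = 9, size_c = 100)
#' @export
two_by_two_trial <- function(trial_id, events_t, size_t, events_c, size_c) {
  trial_id <- as.character(trial_id)
  counts <- c(events_t = events_t, size_t = size_t,
              events_c = events_c, size_c = size_c)
  if (anyNA(counts) || any(counts != round(counts))) {
    stop("trial counts must be non-missing integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  events_t <- counts[1L]; size_t <- counts[2L]
  events_c <- counts[3L]; size_c <- counts[4L]
  if (size_t < 1L || size_c < 1L) {
    stop("arm sizes must be at least 1", call. = FALSE)
  }
  if (events_t < 0L || events_t > size_t || events_c < 0L || events_c > size_c) {
    stop("event counts must satisfy 0 <= events <= arm size", call. = FALSE)
  }
  structure(
    list(trial_id = trial_id,
         events_t = events_t, size_t = size_t,
         events_c = events_c, size_c = size_c,
         total_n = size_t + size_c),
    class = "two_by_two_trial"
  )
}

#' @export
print.two_by_two_trial <- function(x, ...) {
  cat(sprintf("2x2 trial '%s': intervention %d/%d, control %d/%d (n = %d)\n",
              x$trial_id, x$events_t, x$size_t, x$events_c, x$size_c,
              x$total_n))
  invisible(x)
}

#' Pooling configuration for a meta-analysis
#'
#' Specifies the effect measure, the pooling model, the two-sided
#' significance level, and the continuity-correction policy used whenever
#' a trial contains an empty cell. The default (`"rr"`, `"random"`) is
#' random-effects DerSimonian-Laird pooling of relative risks, the most
#' common configuration in meta-analyses of dichotomous clinical
#' outcomes.
#'
#' @param measure `"rr"` (relative risk) or `"or"` (odds ratio).
#' @param model `"random"` (DerSimonian-Laird) or `"fixed"`
#'   (Mantel-Haenszel).
#' @param alpha Two-sided significance level, strictly between 0 and 1.
#' @param zero_cell `"add-half"` (the only implemented policy): trials with
#'   any empty cell get 0.5 added to all four cells for inverse-variance
#'   and DerSimonian-Laird computations; Mantel-Haenszel sums use the raw
#'   counts, which tolerate single empty cells natively; trials with zero
#'   events in both arms are excluded from pooling but retained in the
#'   meta-analysis sample size.
#'
#' @return An object of class `pooling_config`.
#' @examples
#' pooling_config(measure = "rr", model = "fixed", alpha = 0.05)
#' @export
pooling_config <- function(measure = c("rr", "or"),
                           model = c("random", "fixed"),
                           alpha = 0.05,
                           zero_cell = "add-half") {
  measure <- match.arg(measure)
  model <- match.arg(model)
  zero_cell <- match.arg(zero_cell)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  structure(
    list(measure = measure, model = model, alpha = alpha,
         zero_cell = zero_cell),
    class = "pooling_config"
  )
}

#' @export
print.pooling_config <- function(x, ...) {
  cat(sprintf("pooling config: measure = %s, model = %s, alpha = %g, zero-cell = %s\n",
              toupper(x$measure),
              if (x$model == "random") "random (DerSimonian-Laird)"
              else "fixed (Mantel-Haenszel)",
              x$alpha, x$zero_cell))
  invisible(x)
}

#' Construct a meta-analysis specification
#'
#' Bundles an ordered list of 2x2 trials with a pooling configuration.
#' The meta-analysis sample size, used as the denominator of the
#' fragility quotient, is the total number of randomised participants
#' across all included trials (including trials that contribute no events
#' and are therefore excluded from the pooled estimate itself).
#'
#' @param meta_id Character label for the meta-analysis.
#' @param trials List of [two_by_two_trial()] objects, length >= 1, with
#'   unique trial ids.
#' @param config A [pooling_config()].
#'
#' @return An object of class `meta_analysis_spec` with fields `meta_id`,
#'   `trials`, `config` and `sample_size`.
#' @examples
#' meta_analysis_spec(
#'   "example",
#'   list(two_by_two_trial("A", 2, 50, 10, 50),
#'        two_by_two_trial("B", 3, 60, 12, 60)),
#'   pooling_config(model = "fixed")
#' )
#' @export
meta_analysis_spec <- function(meta_id, trials, config = pooling_config()) {
  meta_id <- as.character(meta_id)
  if (!is.list(trials) || length(trials) < 1L) {
    stop("a meta-analysis needs at least one trial", call. = FALSE)
  }
  ok <- vapply(trials, inherits, logical(1), what = "two_by_two_trial")
  if (!all(ok)) {
    stop("all elements of 'trials' must be two_by_two_trial objects",
         call. = FALSE)
  }
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) {
    stop("trial ids must be unique within a meta-analysis", call. = FALSE)
  }
  if (!inherits(config, "pooling_config")) {
    stop("'config' must be a pooling_config object", call. = FALSE)
  }
  structure(
    list(meta_id = meta_id, trials = trials, config = config,
         sample_size = sum(vapply(trials, `[[`, integer(1), "total_n"))),
    class = "meta_analysis_spec"
  )
}

#' @export
print.meta_analysis_spec <- function(x, ...) {
  cat(sprintf("meta-analysis '%s': %d trial(s), %d participants\n",
              x$meta_id, length(x$trials), x$sample_size))
  print(x$config)
  invisible(x)
}

# Internal: counts of a spec as parallel integer vectors.
.spec_counts <- function(meta) {
  list(
    trial_id = vapply(meta$trials, `[[`, character(1), "trial_id"),
    a  = vapply(meta$trials, `[[`, integer(1), "events_t"),
    n1 = vapply(meta$trials, `[[`, integer(1), "size_t"),
    c  = vapply(meta$trials, `[[`, integer(1), "events_c"),
    n2 = vapply(meta$trials, `[[`, integer(1), "size_c")
  )
}

# Internal: rebuild a spec with new event counts (sizes unchanged).
.spec_with_counts <- function(meta, a, c) {
  trials <- meta$trials
  for (i in seq_along(trials)) {
    trials[[i]]$events_t <- as.integer(a[i])
    trials[[i]]$events_c <- as.integer(c[i])
  }
  meta$trials <- trials
  meta
}
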
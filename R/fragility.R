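# Fragility statistics: the single-trial (Walsh) fragility index, the
# meta-analysis fragility index found by greedy minimal event-status
# modification, an exhaustive breadth-first oracle for small instances,
# and the fragility quotient.

.new_fragility_result <- function(index, quotient_pct, trace, terminal,
                                  converged, message = NULL) {
  structure(
    list(index = index, quotient_pct = quotient_pct, trace = trace,
         terminal = terminal, converged = converged, message = message),
    class = "fragility_result"
  )
}

.empty_trace <- function() {
  data.frame(trial_id = character(0), arm = character(0),
             delta = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.fragility_result <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("fragility index = %d (quotient = %.2f%%)\n",
                x$index, x$quotient_pct))
    if (nrow(x$trace)) {
      cat(sprintf("  %d event-status modification(s); terminal p = %.4g\n",
                  nrow(x$trace), x$terminal$p_value))
    }
  } else {
    cat("fragility search did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' Fragility quotient
#'
#' The fragility index divided by the total number of participants in
#' the analysis, multiplied by 100 so that typical values are easy to
#' read as a percentage of the study population.
#'
#' @param index Non-negative integer fragility index.
#' @param sample_size Total number of participants (>= 1).
#' @return The quotient in percent.
#' @examples
#' fragility_quotient(5, 649)  # ~0.77%
#' @export
fragility_quotient <- function(index, sample_size) {
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 0 || index != round(index)) {
    stop("'index' must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(sample_size) || length(sample_size) != 1L ||
      is.na(sample_size) || sample_size < 1 ||
      sample_size != round(sample_size)) {
    stop("'sample_size' must be a single positive integer", call. = FALSE)
  }
  100 * index / sample_size
}

#' Single-trial fragility index (Walsh)
#'
#' Starting from a trial whose two-sided Fisher exact p-value is below
#' `alpha`, repeatedly converts one non-event into an event in the arm
#' currently holding the smaller number of events (ties go to the
#' intervention arm) and recomputes the test, stopping the first time
#' the p-value is at least `alpha`. The fragility index is the number of
#' conversions performed.
#'
#' @param trial A significant [two_by_two_trial()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `fragility_result`: `index`, `quotient_pct` (percent of the
#'   trial's total sample size), `trace` (one row per conversion),
#'   `terminal` (a list holding the terminal Fisher `p_value`) and
#'   `converged`. If the smaller-events arm runs out of non-events before
#'   significance is lost, `converged` is `FALSE` with a diagnostic
#'   message.
#' @examples
#' walsh_fragility(two_by_two_trial("A", 1, 100, 9, 100))
#' @export
walsh_fragility <- function(trial, alpha = 0.05) {
  if (!inherits(trial, "two_by_two_trial")) {
    stop("'trial' must be a two_by_two_trial object", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be strictly between 0 and 1", call. = FALSE)
  }
  a <- trial$events_t; n1 <- trial$size_t
  c <- trial$events_c; n2 <- trial$size_c
  p <- .fisher_p(a, n1, c, n2)
  if (p >= alpha) {
    stop("not fragile-indexable: input not significant (Fisher p = ",
         format(p, digits = 4), " >= alpha)", call. = FALSE)
  }
  trace <- list()
  repeat {
    arm <- if (a <= c) "intervention" else "control"
    if (arm == "intervention") {
      if (a >= n1) {
        return(.new_fragility_result(
          index = length(trace), quotient_pct = NA_real_,
          trace = do.call(rbind, c(list(.empty_trace()), trace)),
          terminal = list(p_value = p), converged = FALSE,
          message = "intervention arm saturated before losing significance"))
      }
      a <- a + 1L
    } else {
      if (c >= n2) {
        return(.new_fragility_result(
          index = length(trace), quotient_pct = NA_real_,
          trace = do.call(rbind, c(list(.empty_trace()), trace)),
          terminal = list(p_value = p), converged = FALSE,
          message = "control arm saturated before losing significance"))
      }
      c <- c + 1L
    }
    trace[[length(trace) + 1L]] <- data.frame(
      trial_id = trial$trial_id, arm = arm, delta = 1L,
      stringsAsFactors = FALSE)
    p <- .fisher_p(a, n1, c, n2)
    if (p >= alpha) break
  }
  index <- length(trace)
  .new_fragility_result(
    index = index,
    quotient_pct = fragility_quotient(index, trial$total_n),
    trace = do.call(rbind, trace),
    terminal = list(p_value = p),
    converged = TRUE)
}

# Candidate null-ward single-event moves for the current counts, in
# deterministic tie-break order: trial input order, intervention arm
# before control arm. `toward` is +1 when the pooled effect must be
# raised towards 1 (current effect < 1) and -1 when it must be lowered.
# moves = "both" allows event additions in the null-ward arm and event
# removals in the opposing arm; "add-only" allows only additions.
.candidate_moves <- function(a, n1, c, n2, toward, moves) {
  out <- list()
  for (i in seq_along(a)) {
    if (toward > 0) {
      if (a[i] < n1[i]) {
        out[[length(out) + 1L]] <- c(i = i, arm = 1L, delta = 1L)
      }
      if (moves == "both" && c[i] > 0L) {
        out[[length(out) + 1L]] <- c(i = i, arm = 2L, delta = -1L)
      }
    } else {
      if (moves == "both" && a[i] > 0L) {
        out[[length(out) + 1L]] <- c(i = i, arm = 1L, delta = -1L)
      }
      if (c[i] < n2[i]) {
        out[[length(out) + 1L]] <- c(i = i, arm = 2L, delta = 1L)
      }
    }
  }
  out
}

.apply_move <- function(a, c, mv) {
  if (mv[["arm"]] == 1L) a[mv[["i"]]] <- a[mv[["i"]]] + mv[["delta"]]
  else c[mv[["i"]]] <- c[mv[["i"]]] + mv[["delta"]]
  list(a = a, c = c)
}

# Walk a single (trial, arm, delta) direction from the current counts,
# re-pooling after each application, and return the number of
# applications until the first non-significant state. Returns Inf when
# the direction saturates, becomes inestimable, or exceeds `cap` (the
# best line found so far; walking further cannot win).
.line_steps <- function(a, c, n1, n2, mv, measure, model, alpha, cap) {
  i <- mv[["i"]]; arm <- mv[["arm"]]; delta <- mv[["delta"]]
  steps <- 0L
  repeat {
    if (steps + 1L >= cap) return(Inf)      # cannot strictly beat cap
    if (arm == 1L) {
      nxt <- a[i] + delta
      if (nxt < 0L || nxt > n1[i]) return(Inf)
      a[i] <- nxt
    } else {
      nxt <- c[i] + delta
      if (nxt < 0L || nxt > n2[i]) return(Inf)
      c[i] <- nxt
    }
    steps <- steps + 1L
    r <- .pool_core(a, n1, c, n2, measure, model, alpha)
    if (is.null(r)) return(Inf)
    if (!.sig(r)) return(steps)
  }
}

#' Meta-analysis fragility index (greedy search)
#'
#' The minimal-perturbation generalisation of the fragility index to a
#' pooled analysis: the number of single-event status modifications,
#' spread over one or more included trials, needed before the pooled
#' confidence interval includes the null ratio of 1.
#'
#' The search is greedy. At each step every candidate single-event
#' modification that moves the pooled effect towards the null is
#' enumerated: when the current pooled effect is below 1, these are
#' converting a non-event to an event in the intervention arm of any
#' trial with spare non-events or converting an event to a non-event in
#' the control arm of any trial with at least one event (mirrored when
#' the effect is above 1). The applied candidate is the direction whose
#' repeated application alone reaches non-significance in the fewest
#' steps — a one-dimensional line search per candidate, re-run from
#' scratch after every single modification, so the path can switch
#' directions as the pooled state moves. (A myopic choice of the single
#' step with the largest recomputed p-value is used as fallback when no
#' single direction can reach the null on its own; on its own that
#' objective is demonstrably non-minimal, because removing events
#' inflates the variance and buys p-value without approaching the null.)
#' Ties are broken by trial input order and then intervention before
#' control arm, so results are bit-reproducible. The pooling — including
#' the DerSimonian-Laird tau2 under the random model — is fully
#' recomputed after every step. On small instances the greedy index is
#' checked against [brute_force_meta_fragility()] in the package's
#' validation suite.
#'
#' @param meta A [meta_analysis_spec()] whose pooled result is
#'   significant under its configuration.
#' @param moves `"both"` (default) to allow event additions in the
#'   null-ward arm and event removals in the opposing arm, or
#'   `"add-only"` to restrict the search to additions, mirroring the
#'   original single-trial definition.
#' @return A `fragility_result`: `index` (number of modifications),
#'   `quotient_pct`, `trace` (one row per modification: trial id, arm,
#'   delta), `terminal` (the final non-significant `pooled_result`) and
#'   `converged` (`FALSE` with a diagnostic if the search exhausts all
#'   candidate moves while still significant).
#' @examples
#' m <- meta_analysis_spec(
#'   "ex",
#'   list(two_by_two_trial("A", 2, 50, 10, 50),
#'        two_by_two_trial("B", 3, 60, 12, 60)),
#'   pooling_config(model = "fixed"))
#' meta_fragility(m)
#' @export
meta_fragility <- function(meta, moves = c("both", "add-only")) {
  if (!inherits(meta, "meta_analysis_spec")) {
    stop("'meta' must be a meta_analysis_spec object", call. = FALSE)
  }
  moves <- match.arg(moves)
  cfg <- meta$config
  cts <- .spec_counts(meta)
  a <- cts$a; n1 <- cts$n1; c <- cts$c; n2 <- cts$n2
  res <- .pool_core(a, n1, c, n2, cfg$measure, cfg$model, cfg$alpha)
  if (is.null(res)) {
    stop("inestimable meta-analysis: every trial has zero events in both arms",
         call. = FALSE)
  }
  if (!.sig(res)) {
    stop("not fragile-indexable: pooled result is not significant (p = ",
         format(res$p_value, digits = 4), ")", call. = FALSE)
  }

  trace <- list()
  max_steps <- sum(n1) + sum(n2)   # hard budget: every event slot flipped once
  repeat {
    toward <- if (res$log_effect < 0) 1L else -1L
    cand <- .candidate_moves(a, n1, c, n2, toward, moves)
    if (!length(cand)) {
      return(.new_fragility_result(
        index = length(trace), quotient_pct = NA_real_,
        trace = do.call(rbind, c(list(.empty_trace()), trace)),
        terminal = structure(res, class = "pooled_result"),
        converged = FALSE,
        message = "no candidate modifications remain while still significant"))
    }
    # primary objective: the direction whose repeated application reaches
    # non-significance in the fewest steps (re-evaluated after every
    # single modification; ties go to the earlier direction in
    # trial-order / intervention-first enumeration)
    best <- NULL
    best_t <- Inf
    for (mv in cand) {
      t <- .line_steps(a, c, n1, n2, mv, cfg$measure, cfg$model, cfg$alpha,
                       cap = best_t)
      if (t < best_t) { best_t <- t; best <- mv }
    }
    if (is.null(best)) {
      # no single direction reaches the null on its own: fall back to the
      # candidate with the largest recomputed p-value for one step
      best_p <- -Inf
      best_res <- NULL
      for (mv in cand) {
        st <- .apply_move(a, c, mv)
        r <- .pool_core(st$a, n1, st$c, n2, cfg$measure, cfg$model, cfg$alpha)
        if (is.null(r)) next
        if (r$p_value > best_p) { best <- mv; best_p <- r$p_value; best_res <- r }
      }
      if (is.null(best)) {
        return(.new_fragility_result(
          index = length(trace), quotient_pct = NA_real_,
          trace = do.call(rbind, c(list(.empty_trace()), trace)),
          terminal = structure(res, class = "pooled_result"),
          converged = FALSE,
          message = "no candidate modifications remain while still significant"))
      }
      st <- .apply_move(a, c, best)
      a <- st$a; c <- st$c
      res <- best_res
    } else {
      st <- .apply_move(a, c, best)
      a <- st$a; c <- st$c
      res <- .pool_core(a, n1, c, n2, cfg$measure, cfg$model, cfg$alpha)
    }
    trace[[length(trace) + 1L]] <- data.frame(
      trial_id = cts$trial_id[best[["i"]]],
      arm = if (best[["arm"]] == 1L) "intervention" else "control",
      delta = as.integer(best[["delta"]]),
      stringsAsFactors = FALSE)
    if (!.sig(res)) break
    if (length(trace) >= max_steps) {
      return(.new_fragility_result(
        index = length(trace), quotient_pct = NA_real_,
        trace = do.call(rbind, trace),
        terminal = structure(res, class = "pooled_result"),
        converged = FALSE,
        message = "step budget exhausted while still significant"))
    }
  }

  res$measure <- cfg$measure; res$model <- cfg$model; res$alpha <- cfg$alpha
  index <- length(trace)
  .new_fragility_result(
    index = index,
    quotient_pct = fragility_quotient(index, meta$sample_size),
    trace = do.call(rbind, trace),
    terminal = structure(res, class = "pooled_result"),
    converged = TRUE)
}

#' Exhaustive fragility index for small meta-analyses
#'
#' Breadth-first search over all count states reachable by null-ward
#' single-event modifications, by total modification count, returning
#' the minimum number of modifications whose state is non-significant.
#' States are deduplicated (the order of modifications does not affect
#' the resulting counts), so the result is the exact minimum over the
#' null-ward move set. Intended as a verification oracle for
#' [meta_fragility()] on small instances; runtime grows combinatorially
#' with trial count and depth.
#'
#' @param meta A significant [meta_analysis_spec()] with at most 4
#'   trials.
#' @param depth_cap Maximum total modifications to explore (default 8).
#' @param moves As in [meta_fragility()].
#' @return A `fragility_result`. If no non-significant state is reachable
#'   within `depth_cap` modifications, `converged` is `FALSE`, `index` is
#'   `NA` and a warning reports the exhausted cap.
#' @export
brute_force_meta_fragility <- function(meta, depth_cap = 8L,
                                       moves = c("both", "add-only")) {
  if (!inherits(meta, "meta_analysis_spec")) {
    stop("'meta' must be a meta_analysis_spec object", call. = FALSE)
  }
  moves <- match.arg(moves)
  if (length(meta$trials) > 4L) {
    stop("brute-force oracle is limited to meta-analyses with at most 4 trials",
         call. = FALSE)
  }
  if (!is.numeric(depth_cap) || depth_cap < 1L || depth_cap > 8L) {
    stop("depth_cap must be between 1 and 8", call. = FALSE)
  }
  cfg <- meta$config
  cts <- .spec_counts(meta)
  n1 <- cts$n1; n2 <- cts$n2
  res0 <- .pool_core(cts$a, n1, cts$c, n2, cfg$measure, cfg$model, cfg$alpha)
  if (is.null(res0)) {
    stop("inestimable meta-analysis: every trial has zero events in both arms",
         call. = FALSE)
  }
  if (!.sig(res0)) {
    stop("not fragile-indexable: pooled result is not significant (p = ",
         format(res0$p_value, digits = 4), ")", call. = FALSE)
  }

  key <- function(a, c) paste(c(a, c), collapse = ",")
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(key(cts$a, cts$c), TRUE, envir = seen)
  # frontier entries: list(a, c, res, path)
  frontier <- list(list(a = cts$a, c = cts$c, res = res0, path = list()))

  for (depth in seq_len(depth_cap)) {
    nxt <- list()
    for (st in frontier) {
      toward <- if (st$res$log_effect < 0) 1L else -1L
      for (mv in .candidate_moves(st$a, n1, st$c, n2, toward, moves)) {
        s2 <- .apply_move(st$a, st$c, mv)
        k2 <- key(s2$a, s2$c)
        if (exists(k2, envir = seen, inherits = FALSE)) next
        assign(k2, TRUE, envir = seen)
        r <- .pool_core(s2$a, n1, s2$c, n2, cfg$measure, cfg$model, cfg$alpha)
        if (is.null(r)) next
        path <- c(st$path, list(data.frame(
          trial_id = cts$trial_id[mv[["i"]]],
          arm = if (mv[["arm"]] == 1L) "intervention" else "control",
          delta = as.integer(mv[["delta"]]),
          stringsAsFactors = FALSE)))
        if (!.sig(r)) {
          r$measure <- cfg$measure; r$model <- cfg$model; r$alpha <- cfg$alpha
          return(.new_fragility_result(
            index = depth,
            quotient_pct = fragility_quotient(depth, meta$sample_size),
            trace = do.call(rbind, path),
            terminal = structure(r, class = "pooled_result"),
            converged = TRUE))
        }
        nxt[[length(nxt) + 1L]] <- list(a = s2$a, c = s2$c, res = r,
                                        path = path)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  warning("no non-significant state within depth cap ", depth_cap,
          call. = FALSE)
  .new_fragility_result(
    index = NA_integer_, quotient_pct = NA_real_, trace = .empty_trace(),
    terminal = NULL, converged = FALSE,
    message = paste("no solution within depth cap", depth_cap))
}

#' Replay a modification trace on a meta-analysis
#'
#' Applies the modifications recorded in a `fragility_result` trace to
#' the original meta-analysis, returning the modified specification.
#' Useful for verifying that a reported fragility index reproduces its
#' terminal pooled state.
#'
#' @param meta The original [meta_analysis_spec()].
#' @param trace A trace data frame (`trial_id`, `arm`, `delta`), possibly
#'   truncated.
#' @return A [meta_analysis_spec()] with modified event counts.
#' @export
apply_trace <- function(meta, trace) {
  if (!inherits(meta, "meta_analysis_spec")) {
    stop("'meta' must be a meta_analysis_spec object", call. = FALSE)
  }
  cts <- .spec_counts(meta)
  a <- cts$a; c <- cts$c
  for (j in seq_len(nrow(trace))) {
    i <- match(trace$trial_id[j], cts$trial_id)
    if (is.na(i)) stop("trace refers to unknown trial ", trace$trial_id[j],
                       call. = FALSE)
    if (trace$arm[j] == "intervention") a[i] <- a[i] + trace$delta[j]
    else c[i] <- c[i] + trace$delta[j]
  }
  if (any(a < 0L) || any(a > cts$n1) || any(c < 0L) || any(c > cts$n2)) {
    stop("trace produces counts outside the valid range", call. = FALSE)
  }
  .spec_with_counts(meta, a, c)
}
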
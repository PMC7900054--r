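# Two-sided Fisher exact test, minimum-likelihood rule.
#
# The fragility search re-evaluates the test after every single-event
# modification, so the p-value is computed directly from the
# hypergeometric pmf rather than through stats::fisher.test (which
# carries the full htest machinery). The convention is the mainstream
# one: sum the probabilities of all tables with the observed margins
# whose hypergeometric probability does not exceed that of the observed
# table, with a relative tolerance of 1e-7 on the comparison to absorb
# floating-point noise among tied tables.

# Internal scalar kernel on raw counts.
.fisher_p <- function(a, n1, c, n2) {
  m <- a + c                       # total events; margins fixed
  if (m == 0L || m == n1 + n2) return(1)
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  x <- lo:hi
  d <- stats::dhyper(x, n1, n2, m)
  p <- sum(d[d <= d[a - lo + 1L] * (1 + 1e-7)])
  min(p, 1)
}

#' Two-sided Fisher exact test for a 2x2 trial
#'
#' Computes the two-sided Fisher exact p-value for the association
#' between arm and outcome, under the minimum-likelihood rule: the sum of
#' the probabilities of all tables with the same margins whose
#' hypergeometric probability is at most that of the observed table
#' (within a relative tolerance of 1e-7). This matches the convention of
#' [stats::fisher.test()].
#'
#' A table with no events at all (or events in every participant) admits
#' only one table with its margins, so the p-value is 1.
#'
#' @param trial A [two_by_two_trial()].
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(two_by_two_trial("A", 1, 100, 9, 100))
#' @export
fisher_exact_two_sided <- function(trial) {
  if (!inherits(trial, "two_by_two_trial")) {
    stop("'trial' must be a two_by_two_trial object", call. = FALSE)
  }
  .fisher_p(trial$events_t, trial$size_t, trial$events_c, trial$size_c)
}
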
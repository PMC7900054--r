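# Pooling engines: fixed-effect Mantel-Haenszel and random-effects
# DerSimonian-Laird, for relative risks and odds ratios on 2x2 counts.
#
# The fragility search recomputes the pooled model after every candidate
# single-event modification, so the core estimator works on plain count
# vectors with no object overhead; pool() is the validated public
# wrapper.

# Per-trial log effects and variances with the add-half zero-cell
# policy: 0.5 added to all four cells of any trial with an empty cell.
.trial_effects <- function(a, n1, c, n2, measure) {
  b <- n1 - a
  d <- n2 - c
  z <- (a == 0L | b == 0L | c == 0L | d == 0L)
  a2 <- a + 0.5 * z; b2 <- b + 0.5 * z; c2 <- c + 0.5 * z; d2 <- d + 0.5 * z
  if (measure == "rr") {
    n1c <- a2 + b2; n2c <- c2 + d2
    y <- log((a2 / n1c) / (c2 / n2c))
    v <- 1 / a2 - 1 / n1c + 1 / c2 - 1 / n2c
  } else {
    y <- log(a2 * d2 / (b2 * c2))
    v <- 1 / a2 + 1 / b2 + 1 / c2 + 1 / d2
  }
  list(y = y, v = v)
}

# Core pooled estimate on count vectors. Returns NULL when no trial is
# estimable (zero events in both arms everywhere). Trials with zero
# events in both arms contribute no information about a ratio measure
# and are dropped before pooling.
.pool_core <- function(a, n1, c, n2, measure, model, alpha) {
  keep <- !(a == 0L & c == 0L)
  if (!any(keep)) return(NULL)
  a <- a[keep]; n1 <- n1[keep]; c <- c[keep]; n2 <- n2[keep]
  k <- length(a)

  eff <- .trial_effects(a, n1, c, n2, measure)
  w_iv <- 1 / eff$v
  y_iv <- sum(w_iv * eff$y) / sum(w_iv)
  q_stat <- sum(w_iv * (eff$y - y_iv)^2)
  tau2 <- 0

  if (model == "fixed") {
    N <- n1 + n2
    if (measure == "rr") {
      # Mantel-Haenszel RR with Greenland-Robins variance
      R <- sum(a * n2 / N)
      S <- sum(c * n1 / N)
      if (R == 0 || S == 0) {
        # degenerate Mantel-Haenszel sums (all events in one arm across
        # every trial): fall back to corrected counts throughout
        z <- 0.5
        ac <- a + z; cc <- c + z; n1c <- n1 + 2 * z; n2c <- n2 + 2 * z
        Nc <- n1c + n2c
        R <- sum(ac * n2c / Nc); S <- sum(cc * n1c / Nc)
        P <- (n1c * n2c * (ac + cc) - ac * cc * Nc) / Nc^2
        theta <- log(R / S)
        var <- sum(P) / (R * S)
      } else {
        P <- (n1 * n2 * (a + c) - a * c * N) / N^2
        theta <- log(R / S)
        var <- sum(P) / (R * S)                  # Greenland-Robins
      }
    } else {
      b <- n1 - a; d <- n2 - c
      Rk <- a * d / N; Sk <- b * c / N
      R <- sum(Rk); S <- sum(Sk)
      if (R == 0 || S == 0) {
        z <- 0.5
        ac <- a + z; bc <- b + z; cc <- c + z; dc <- d + z
        Nc <- N + 4 * z
        Rk <- ac * dc / Nc; Sk <- bc * cc / Nc
        R <- sum(Rk); S <- sum(Sk)
        P <- (ac + dc) / Nc; Q <- (bc + cc) / Nc
      } else {
        P <- (a + d) / N; Q <- (b + c) / N
      }
      theta <- log(R / S)
      # Robins-Breslow-Greenland variance
      var <- sum(P * Rk) / (2 * R^2) +
        sum(P * Sk + Q * Rk) / (2 * R * S) +
        sum(Q * Sk) / (2 * S^2)
    }
  } else {
    if (k > 1L) {
      denom <- sum(w_iv) - sum(w_iv^2) / sum(w_iv)
      tau2 <- max(0, (q_stat - (k - 1)) / denom)
    }
    w_re <- 1 / (eff$v + tau2)
    theta <- sum(w_re * eff$y) / sum(w_re)
    var <- 1 / sum(w_re)
  }

  se <- sqrt(var)
  zc <- stats::qnorm(1 - alpha / 2)
  list(log_effect = theta, se = se,
       ci_low = exp(theta - zc * se), ci_high = exp(theta + zc * se),
       p_value = 2 * stats::pnorm(-abs(theta / se)),
       tau2 = tau2, q_stat = q_stat, k = k)
}

#' Pool a meta-analysis of 2x2 trials
#'
#' Combines the trials of a meta-analysis into a pooled ratio estimate
#' with a Wald confidence interval and two-sided p-value on the log
#' scale.
#'
#' The fixed-effect model is the Mantel-Haenszel pooled relative risk or
#' odds ratio, with the Greenland-Robins (RR) or Robins-Breslow-Greenland
#' (OR) variance for the log effect. The random-effects model uses
#' inverse-variance weights `1 / (v_i + tau2)` with the DerSimonian-Laird
#' moment estimator `tau2 = max(0, (Q - (k - 1)) / (sum(w) -
#' sum(w^2)/sum(w)))` computed on the fixed inverse-variance weights,
#' re-estimated from scratch on whatever counts are supplied. Trials with
#' any empty cell enter the inverse-variance computations with 0.5 added
#' to all four cells; trials with zero events in both arms are excluded
#' from pooling (they carry no information about a ratio) but still count
#' towards the meta-analysis sample size.
#'
#' @param meta A [meta_analysis_spec()].
#' @return An object of class `pooled_result` with fields `log_effect`,
#'   `se`, `ci_low`, `ci_high` (on the ratio scale), `p_value`, `tau2`
#'   (0 under the fixed model), `q_stat` (Cochran's Q from the
#'   inverse-variance weights), `k` (trials contributing to the pool),
#'   plus the `measure`, `model` and `alpha` used.
#' @examples
#' m <- meta_analysis_spec(
#'   "ex", list(two_by_two_trial("A", 10, 100, 20, 100)),
#'   pooling_config(model = "fixed"))
#' pool(m)
#' @export
pool <- function(meta) {
  if (!inherits(meta, "meta_analysis_spec")) {
    stop("'meta' must be a meta_analysis_spec object", call. = FALSE)
  }
  cts <- .spec_counts(meta)
  cfg <- meta$config
  res <- .pool_core(cts$a, cts$n1, cts$c, cts$n2,
                    cfg$measure, cfg$model, cfg$alpha)
  if (is.null(res)) {
    stop("inestimable meta-analysis: every trial has zero events in both arms",
         call. = FALSE)
  }
  res$measure <- cfg$measure
  res$model <- cfg$model
  res$alpha <- cfg$alpha
  class(res) <- "pooled_result"
  res
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "pooled %s (%s model, k = %d): %.3f [%.3f, %.3f], p = %.4g, tau2 = %.4g\n",
    toupper(x$measure), x$model, x$k, exp(x$log_effect),
    x$ci_low, x$ci_high, x$p_value, x$tau2))
  invisible(x)
}

#' Is a pooled result statistically significant?
#'
#' A pooled result is significant when its confidence interval excludes
#' the null ratio of 1; an interval touching 1 exactly counts as
#' including the null (the conservative boundary convention, mirroring
#' the "p at least equal to alpha" stopping rule of the fragility
#' search). Because the interval and the p-value come from the same Wald
#' construction, this is equivalent to `p_value < alpha` up to
#' floating-point rounding.
#'
#' @param result A `pooled_result` from [pool()].
#' @return `TRUE` or `FALSE`.
#' @export
is_significant <- function(result) {
  if (!inherits(result, "pooled_result") &&
      !all(c("ci_low", "ci_high") %in% names(result))) {
    stop("'result' must be a pooled_result", call. = FALSE)
  }
  isTRUE(result$ci_low > 1) || isTRUE(result$ci_high < 1)
}

# Internal significance check on a .pool_core list.
.sig <- function(res) res$ci_low > 1 || res$ci_high < 1
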
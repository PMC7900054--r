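# Corpus-level meta-research statistics: medians with interquartile
# ranges, cumulative-count distribution curves, and Pearson correlations
# (with Fisher-z confidence intervals) between fragility measures and
# pooled p-values.

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation between two vectors, with a confidence
#' interval from the Fisher z-transform (variance `1/(n-3)`) and a
#' two-sided p-value from the t-statistic `r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @param conf Confidence level (default 0.95).
#' @return A list with `r`, `ci_low`, `ci_high`, `p`, and `n`.
#' @examples
#' pearson_with_ci(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported",
                                 call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1) {
    stop("conf must be strictly between 0 and 1", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
}

# Empirical cumulative count of records at or below each distinct value.
.cumulative_curve <- function(values) {
  v <- sort(unique(values))
  data.frame(value = v,
             cum_count = vapply(v, function(t) sum(values <= t), numeric(1)))
}

#' Summarise a corpus of fragility results
#'
#' Computes the corpus-level statistics for a set of analysed
#' meta-analyses: median, quartiles (linear-interpolation convention,
#' i.e. R's default type-7 quantiles) and range for the fragility index
#' and for the fragility quotient; cumulative-count curves over the
#' distinct observed values of each; and Pearson correlations (with
#' Fisher-z confidence intervals) between each fragility measure and the
#' pooled p-values.
#'
#' @param records A data frame with one row per meta-analysis and columns
#'   `meta_id`, `index`, `quotient_pct`, `p_value`, `sample_size`.
#' @param conf Confidence level for the correlation intervals.
#' @param scale `"raw"` (default) correlates the fragility measures on
#'   their natural scale; `"log2"` applies a base-2 logarithm to the
#'   fragility measures first (the scale sometimes used to display
#'   right-skewed fragility distributions).
#' @return An object of class `corpus_summary`: `n_records`, per-measure
#'   summary blocks (`median`, `q25`, `q75`, `min`, `max`), cumulative
#'   curves (`cumsum_index`, `cumsum_quotient`), and correlation results
#'   `pearson_index_p`, `pearson_quotient_p` (each `NULL` when fewer
#'   than 3 records or a constant measure makes the correlation
#'   undefined).
#' @export
summarize_corpus <- function(records, conf = 0.95,
                             scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  needed <- c("meta_id", "index", "quotient_pct", "p_value", "sample_size")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("'records' must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) < 1L) stop("empty corpus", call. = FALSE)

  five <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = q[2], q25 = q[1], q75 = q[3], min = min(v), max = max(v))
  }
  xf <- function(v) if (scale == "log2") log2(v) else v
  corr <- function(v) {
    if (nrow(records) < 3L || stats::sd(v) == 0 ||
        stats::sd(records$p_value) == 0) return(NULL)
    pearson_with_ci(xf(v), records$p_value, conf = conf)
  }

  structure(
    list(n_records = nrow(records),
         index = five(records$index),
         quotient_pct = five(records$quotient_pct),
         cumsum_index = .cumulative_curve(records$index),
         cumsum_quotient = .cumulative_curve(records$quotient_pct),
         pearson_index_p = corr(records$index),
         pearson_quotient_p = corr(records$quotient_pct),
         conf = conf, scale = scale),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("corpus of %d significant meta-analyses\n", x$n_records))
  cat(sprintf("  fragility index:    median %g (Q25-Q75 %g-%g, range %g-%g)\n",
              x$index$median, x$index$q25, x$index$q75,
              x$index$min, x$index$max))
  cat(sprintf("  fragility quotient: median %.2f%% (Q25-Q75 %.2f-%.2f%%, range %.2f-%.2f%%)\n",
              x$quotient_pct$median, x$quotient_pct$q25, x$quotient_pct$q75,
              x$quotient_pct$min, x$quotient_pct$max))
  pr <- function(lbl, cr) {
    if (is.null(cr)) return(invisible(NULL))
    cat(sprintf("  Pearson R (%s vs pooled p): %.2f (%g%% CI %.2f to %.2f, p = %.4g)\n",
                lbl, cr$r, 100 * x$conf, cr$ci_low, cr$ci_high, cr$p))
  }
  pr("index", x$pearson_index_p)
  pr("quotient", x$pearson_quotient_p)
  invisible(x)
}
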
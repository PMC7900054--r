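# Synthetic meta-analysis corpora: binomial 2x2 trials with lognormal
# arm sizes, Beta control event rates, Normal effect heterogeneity, and
# the significance-based inclusion filter that defines the corpus.

#' Configure a synthetic corpus model
#'
#' Defines the generative model for a corpus of meta-analyses of
#' dichotomous outcomes. Defaults emulate a meta-research survey corpus
#' of 79 included (i.e. significant) meta-analyses drawn from clinical
#' literature with heterogeneous trial counts, arm sizes, baseline risks
#' and effect sizes: trials per meta-analysis uniform on 2-10, arm sizes
#' lognormal with median 60 and log-sd 0.6 truncated to \[10, 2000\],
#' control event rates Beta with mean 0.15 and concentration 10
#' truncated to \[0.01, 0.6\], a meta-analysis-level true log relative
#' risk Normal(log 0.6, 0.3), and between-trial heterogeneity of sd 0.2
#' on the log relative risk.
#'
#' @param n_meta Number of included (significant) meta-analyses to
#'   collect.
#' @param trials_range Integer range (min, max) of trials per
#'   meta-analysis, drawn uniformly.
#' @param arm_size_meanlog,arm_size_sdlog Lognormal parameters for arm
#'   sizes.
#' @param arm_size_range Truncation bounds for arm sizes.
#' @param control_rate_mean,control_rate_conc Beta mean and concentration
#'   for the control-arm event rate (shape1 = mean * conc,
#'   shape2 = (1 - mean) * conc).
#' @param control_rate_range Truncation bounds for the control rate.
#' @param log_rr_mean,log_rr_sd Normal parameters of the meta-analysis
#'   level true log relative risk.
#' @param tau Between-trial standard deviation of the log relative risk.
#' @param alpha Two-sided significance level used by the inclusion
#'   filter.
#' @param config A [pooling_config()] used to pool candidates (defaults
#'   to random-effects DerSimonian-Laird relative risks at `alpha`).
#' @param seed Master integer seed; child seeds for each candidate
#'   meta-analysis are derived from it (see [simulate_corpus()]).
#' @return An object of class `corpus_model`.
#' @export
corpus_model <- function(n_meta = 79L,
                         trials_range = c(2L, 10L),
                         arm_size_meanlog = log(60),
                         arm_size_sdlog = 0.6,
                         arm_size_range = c(10L, 2000L),
                         control_rate_mean = 0.15,
                         control_rate_conc = 10,
                         control_rate_range = c(0.01, 0.6),
                         log_rr_mean = log(0.6),
                         log_rr_sd = 0.3,
                         tau = 0.2,
                         alpha = 0.05,
                         config = NULL,
                         seed = 20210116L) {
  if (is.null(config)) config <- pooling_config(alpha = alpha)
  stopifnot(n_meta >= 1, trials_range[1] >= 1,
            trials_range[2] >= trials_range[1],
            arm_size_range[1] >= 1, arm_size_range[2] >= arm_size_range[1],
            control_rate_range[1] > 0, control_rate_range[2] < 1,
            control_rate_conc > 0, tau >= 0, alpha > 0, alpha < 1)
  structure(
    list(n_meta = as.integer(n_meta),
         trials_range = as.integer(trials_range),
         arm_size_meanlog = arm_size_meanlog,
         arm_size_sdlog = arm_size_sdlog,
         arm_size_range = as.integer(arm_size_range),
         control_rate_mean = control_rate_mean,
         control_rate_conc = control_rate_conc,
         control_rate_range = control_rate_range,
         log_rr_mean = log_rr_mean, log_rr_sd = log_rr_sd,
         tau = tau, alpha = alpha, config = config,
         seed = as.integer(seed)),
    class = "corpus_model"
  )
}

#' @export
print.corpus_model <- function(x, ...) {
  cat(sprintf(
    "synthetic corpus model: %d significant meta-analyses, %d-%d trials each, seed %d\n",
    x$n_meta, x$trials_range[1], x$trials_range[2], x$seed))
  cat(sprintf(
    "  arm sizes ~ lognormal(meanlog %.3g, sdlog %.3g) in [%d, %d]; control rate ~ Beta(mean %.3g, conc %.3g) in [%.3g, %.3g]\n",
    x$arm_size_meanlog, x$arm_size_sdlog, x$arm_size_range[1],
    x$arm_size_range[2], x$control_rate_mean, x$control_rate_conc,
    x$control_rate_range[1], x$control_rate_range[2]))
  cat(sprintf("  true log RR ~ Normal(%.3g, %.3g), between-trial tau = %.3g, alpha = %g\n",
              x$log_rr_mean, x$log_rr_sd, x$tau, x$alpha))
  invisible(x)
}

#' Simulate one binomial 2x2 trial
#'
#' Draws control-arm events from Binomial(`size_c`, `p_c`) and
#' intervention-arm events from Binomial(`size_t`, `p_c * exp(log_rr)`)
#' using the current R random-number stream, so results are
#' deterministic given the RNG state (seed it with [set.seed()]).
#'
#' @param size_t,size_c Arm sizes (positive integers).
#' @param p_c Control-arm event probability.
#' @param log_rr True log relative risk; `p_c * exp(log_rr)` must not
#'   exceed 1.
#' @param trial_id Label for the trial.
#' @return A [two_by_two_trial()].
#' @export
simulate_trial <- function(size_t, size_c, p_c, log_rr, trial_id = "sim") {
  if (!is.numeric(p_c) || p_c < 0 || p_c > 1) {
    stop("p_c must be a probability", call. = FALSE)
  }
  p_t <- p_c * exp(log_rr)
  if (p_t > 1 + 1e-12) {
    stop("implied intervention risk exceeds 1 (p_c * exp(log_rr) = ",
         format(p_t, digits = 4), ")", call. = FALSE)
  }
  p_t <- min(p_t, 1)
  two_by_two_trial(trial_id,
                   events_t = stats::rbinom(1L, size_t, p_t),
                   size_t = size_t,
                   events_c = stats::rbinom(1L, size_c, p_c),
                   size_c = size_c)
}

# Deterministic child seed for candidate i under master seed s: a fixed
# affine rule modulo the largest 32-bit prime, so corpora are extensible
# (candidate i always gets the same stream regardless of how many
# candidates are eventually drawn).
.child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

# Draw one candidate meta-analysis from the model (no inclusion filter).
.draw_candidate <- function(model, meta_id, child_seed) {
  set.seed(child_seed)
  k <- sample(model$trials_range[1]:model$trials_range[2], 1L)
  mu <- stats::rnorm(1L, model$log_rr_mean, model$log_rr_sd)
  trials <- vector("list", k)
  for (j in seq_len(k)) {
    n1 <- round(stats::rlnorm(1L, model$arm_size_meanlog, model$arm_size_sdlog))
    n2 <- round(stats::rlnorm(1L, model$arm_size_meanlog, model$arm_size_sdlog))
    n1 <- min(max(n1, model$arm_size_range[1]), model$arm_size_range[2])
    n2 <- min(max(n2, model$arm_size_range[1]), model$arm_size_range[2])
    p_c <- stats::rbeta(1L,
                        model$control_rate_mean * model$control_rate_conc,
                        (1 - model$control_rate_mean) * model$control_rate_conc)
    p_c <- min(max(p_c, model$control_rate_range[1]),
               model$control_rate_range[2])
    lrr <- mu + stats::rnorm(1L, 0, model$tau)
    # keep the implied intervention risk a proper probability
    lrr <- min(lrr, log(0.99 / p_c))
    trials[[j]] <- simulate_trial(n1, n2, p_c, lrr,
                                  trial_id = sprintf("%s_t%02d", meta_id, j))
  }
  meta_analysis_spec(meta_id, trials, model$config)
}

#' Simulate a corpus of significant meta-analyses
#'
#' Draws candidate meta-analyses from the generative model, pools each
#' one under the model's configuration, and retains only candidates
#' whose pooled confidence interval excludes 1 — the inclusion rule of a
#' meta-research survey restricted to statistically significant
#' meta-analyses — until `n_meta` have been collected.
#'
#' Each candidate `i` is generated from its own child seed
#' `(seed + 1000003 * i) mod 2147483647`, so a corpus is fully
#' reproducible from the master seed and remains stable under extension
#' to more candidates.
#'
#' @param model A [corpus_model()].
#' @return An object of class `synthetic_corpus`: `specs` (list of
#'   [meta_analysis_spec()], all significant), `model`, `n_candidates`
#'   and `n_rejected`.
#' @export
simulate_corpus <- function(model) {
  if (!inherits(model, "corpus_model")) {
    stop("'model' must be a corpus_model object", call. = FALSE)
  }
  specs <- vector("list", model$n_meta)
  accepted <- 0L
  i <- 0L
  while (accepted < model$n_meta) {
    i <- i + 1L
    if (i > 1000L && accepted < i / 1000) {
      stop("inclusion filter acceptance rate below 1/1000; ",
           "generative parameters are degenerate", call. = FALSE)
    }
    cand <- .draw_candidate(model, sprintf("meta%04d", i), .child_seed(model$seed, i))
    cts <- .spec_counts(cand)
    res <- .pool_core(cts$a, cts$n1, cts$c, cts$n2,
                      model$config$measure, model$config$model,
                      model$config$alpha)
    if (!is.null(res) && .sig(res)) {
      accepted <- accepted + 1L
      specs[[accepted]] <- cand
    }
  }
  structure(
    list(specs = specs, model = model,
         n_candidates = i, n_rejected = i - accepted),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "synthetic corpus: %d significant meta-analyses (from %d candidates, %d rejected), seed %d\n",
    length(x$specs), x$n_candidates, x$n_rejected, x$model$seed))
  invisible(x)
}

#' The two-study fragility contrast
#'
#' A constructed pair of hypothetical trials illustrating how the
#' fragility index penalises small studies: a small trial with a
#' relative risk reduction of about 89% and a large trial with a
#' reduction of about 20%, both with two-sided Fisher exact p-values
#' near 0.02. Despite the far larger treatment effect, the small trial's
#' fragility index is much lower than the large trial's.
#'
#' The tables were fixed by a deterministic scan over event counts at
#' arm sizes 100 (small) and 1000 (large) for the first table meeting
#' the constraints `RRR` in \[0.85, 0.92\] (small) or \[0.17, 0.23\]
#' (large) with Fisher p in \[0.015, 0.03\]; the search is reproduced by
#' the internal helper `.find_contrast_tables()` and its output is
#' frozen here.
#'
#' @return A named list with elements `small` and `large`, each a
#'   [two_by_two_trial()].
#' @examples
#' ct <- construct_two_study_contrast()
#' fisher_exact_two_sided(ct$small)
#' fisher_exact_two_sided(ct$large)
#' @export
construct_two_study_contrast <- function() {
  list(
    small = two_by_two_trial("small", events_t = 1L, size_t = 100L,
                             events_c = 9L, size_c = 100L),
    large = two_by_two_trial("large", events_t = 114L, size_t = 1000L,
                             events_c = 148L, size_c = 1000L)
  )
}

# Deterministic construction search behind construct_two_study_contrast:
# for equal arm sizes n, scans control event counts up to a 30% baseline
# rate and intervention counts in ascending order, returning the first
# table meeting the relative-risk-reduction window with two-sided Fisher
# p in [0.015, 0.03].
.find_contrast_tables <- function(rrr_window, n) {
  for (ec in 1:floor(0.3 * n)) {
    for (et in 0:ec) {
      rrr <- 1 - et / ec
      if (rrr < rrr_window[1] || rrr > rrr_window[2]) next
      p <- .fisher_p(et, n, ec, n)
      if (p >= 0.015 && p <= 0.03) {
        return(two_by_two_trial(sprintf("n%d", n), et, n, ec, n))
      }
    }
  }
  NULL
}
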
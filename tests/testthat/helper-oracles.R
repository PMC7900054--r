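# Independent oracles and random-instance generators shared across the
# suite. These deliberately avoid the package's own computational paths:
# the Fisher oracle enumerates the hypergeometric pmf from binomial
# coefficients, and pooling cross-checks go through metafor.

# Two-sided Fisher p by direct enumeration over all tables with the
# observed margins, probabilities from lchoose (minimum-likelihood rule,
# same 1e-7 relative tolerance convention as mainstream software).
oracle_fisher_p <- function(a, n1, c, n2) {
  m <- a + c
  if (m == 0 || m == n1 + n2) return(1)
  lo <- max(0, m - n2); hi <- min(m, n1)
  x <- lo:hi
  lp <- lchoose(n1, x) + lchoose(n2, m - x) - lchoose(n1 + n2, m)
  p <- exp(lp)
  min(sum(p[p <= p[a - lo + 1] * (1 + 1e-7)]), 1)
}

# Random 2x2 table with arm sizes up to max_n.
rand_trial <- function(max_n = 60, id = "t") {
  n1 <- sample(2:max_n, 1L)
  n2 <- sample(2:max_n, 1L)
  two_by_two_trial(id, sample(0:n1, 1L), n1, sample(0:n2, 1L), n2)
}

# Random trial that is significant by the two-sided Fisher test:
# draws from an effectful binomial model until significant.
rand_sig_trial <- function(alpha = 0.05, max_n = 200, id = "t") {
  repeat {
    n <- sample(30:max_n, 1L)
    p_c <- runif(1, 0.1, 0.5)
    rr <- runif(1, 0.15, 0.6)
    tr <- two_by_two_trial(id, rbinom(1L, n, p_c * rr), n,
                           rbinom(1L, n, p_c), n)
    if (fisher_exact_two_sided(tr) < alpha) return(tr)
  }
}

# Random meta-analysis with k trials (not necessarily significant).
rand_meta <- function(k = NULL, max_arm = 60, config = pooling_config(),
                      rr_range = c(0.2, 0.9), id = "m") {
  if (is.null(k)) k <- sample(1:3, 1L)
  trials <- lapply(seq_len(k), function(j) {
    n1 <- sample(10:max_arm, 1L); n2 <- sample(10:max_arm, 1L)
    p_c <- runif(1, 0.15, 0.5)
    rr <- runif(1, rr_range[1], rr_range[2])
    two_by_two_trial(sprintf("%s_t%d", id, j),
                     rbinom(1L, n1, min(p_c * rr, 1)), n1,
                     rbinom(1L, n2, p_c), n2)
  })
  meta_analysis_spec(id, trials, config)
}

# Random significant meta-analysis (pooled CI excludes 1).
rand_sig_meta <- function(k = NULL, max_arm = 60,
                          config = pooling_config(), id = "m") {
  repeat {
    m <- rand_meta(k = k, max_arm = max_arm, config = config, id = id)
    res <- tryCatch(pool(m), error = function(e) NULL)
    if (!is.null(res) && is_significant(res)) return(m)
  }
}

# The three-trial pooling fixture used for the metafor-frozen regression
# values.
fixture_meta3 <- function(model = "fixed") {
  meta_analysis_spec(
    "fixture3",
    list(two_by_two_trial("t1", 12, 120, 24, 118),
         two_by_two_trial("t2", 5, 60, 9, 61),
         two_by_two_trial("t3", 30, 300, 41, 295)),
    pooling_config(measure = "rr", model = model))
}
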
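# Fragility statistics: the Walsh single-trial index, the greedy
# meta-analysis index against the exhaustive oracle, quotients, and the
# structural properties of every returned result.

test_that("Walsh index of the 1/100 vs 9/100 trial is 1 (frozen oracle)", {
  res <- walsh_fragility(two_by_two_trial("a", 1, 100, 9, 100))
  expect_equal(res$index, 1L)
  expect_true(res$converged)
  expect_gte(res$terminal$p_value, 0.05)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$quotient_pct, 100 * 1 / 200)
})

test_that("non-significant input is rejected, not assigned index 0", {
  expect_error(walsh_fragility(two_by_two_trial("a", 5, 10, 5, 10)),
               "not fragile-indexable")
  m <- meta_analysis_spec("m", list(two_by_two_trial("a", 10, 100, 11, 100)),
                          pooling_config(model = "fixed"))
  expect_error(meta_fragility(m), "not fragile-indexable")
  expect_error(brute_force_meta_fragility(m), "not fragile-indexable")
})

test_that("Walsh stopping rule holds on random significant trials", {
  set.seed(31)
  for (i in 1:100) {
    tr <- rand_sig_trial(max_n = 150)
    res <- walsh_fragility(tr)
    if (!res$converged) next
    expect_gte(res$index, 1L)
    # replay with the independent enumeration oracle: terminal not
    # significant, one step earlier still significant
    a <- tr$events_t; cc <- tr$events_c
    for (j in seq_len(nrow(res$trace))) {
      if (res$trace$arm[j] == "intervention") a <- a + 1L else cc <- cc + 1L
      p <- oracle_fisher_p(a, tr$size_t, cc, tr$size_c)
      if (j < nrow(res$trace)) expect_lt(p, 0.05) else expect_gte(p, 0.05)
    }
    expect_equal(res$terminal$p_value,
                 oracle_fisher_p(a, tr$size_t, cc, tr$size_c),
                 tolerance = 1e-12)
  }
})

test_that("fragility quotient is plain percent arithmetic", {
  expect_equal(fragility_quotient(5, 1000), 0.5)
  expect_equal(fragility_quotient(0, 37), 0)
  expect_equal(round(fragility_quotient(5, 649), 2), 0.77)
  expect_error(fragility_quotient(5, 0), "positive integer")
  expect_error(fragility_quotient(-1, 10), "non-negative")
  expect_error(fragility_quotient(2.5, 10), "non-negative integer")
})

test_that("greedy meta-fragility matches the exhaustive oracle on the
           frozen fixtures", {
  m1 <- meta_analysis_spec("m1", list(two_by_two_trial("A", 1, 100, 9, 100)),
                           pooling_config(model = "fixed"))
  g1 <- meta_fragility(m1)
  b1 <- brute_force_meta_fragility(m1)
  expect_equal(g1$index, 1L)   # frozen: independent metafor-based BFS
  expect_equal(b1$index, 1L)

  m2 <- meta_analysis_spec(
    "m2",
    list(two_by_two_trial("A", 2, 50, 10, 50),
         two_by_two_trial("B", 3, 60, 12, 60)),
    pooling_config(model = "fixed"))
  g2 <- meta_fragility(m2)
  b2 <- brute_force_meta_fragility(m2)
  expect_equal(g2$index, 7L)   # frozen: independent metafor-based BFS
  expect_equal(b2$index, 7L)
  expect_false(is_significant(g2$terminal))
  expect_false(is_significant(b2$terminal))
})

test_that("greedy equals the oracle on random small meta-analyses", {
  set.seed(32)
  n_checked <- 0L
  while (n_checked < 60L) {
    cfg <- pooling_config(model = sample(c("fixed", "random"), 1))
    m <- rand_sig_meta(k = sample(1:3, 1), max_arm = 60, config = cfg)
    b <- suppressWarnings(brute_force_meta_fragility(m, depth_cap = 6L))
    if (!b$converged) next
    g <- meta_fragility(m)
    expect_true(g$converged)
    expect_equal(g$index, b$index)
    n_checked <- n_checked + 1L
  }
})

test_that("every converged result is locally minimal and its trace
           replays to the terminal state", {
  set.seed(33)
  for (i in 1:40) {
    cfg <- pooling_config(model = sample(c("fixed", "random"), 1))
    m <- rand_sig_meta(k = sample(1:3, 1), max_arm = 60, config = cfg)
    res <- meta_fragility(m)
    if (!res$converged) next
    expect_equal(res$index, nrow(res$trace))
    # full replay reproduces the terminal pooled state
    replayed <- pool(apply_trace(m, res$trace))
    expect_false(is_significant(replayed))
    expect_equal(replayed$log_effect, res$terminal$log_effect,
                 tolerance = 1e-12)
    expect_equal(replayed$p_value, res$terminal$p_value, tolerance = 1e-12)
    # dropping the last modification leaves a significant state
    if (res$index > 1) {
      trunc <- pool(apply_trace(m, res$trace[-nrow(res$trace), ]))
      expect_true(is_significant(trunc))
    } else {
      expect_true(is_significant(pool(m)))
    }
  }
})

test_that("restricting the move set to additions can only raise the index", {
  set.seed(34)
  for (i in 1:25) {
    m <- rand_sig_meta(k = sample(1:2, 1), max_arm = 50,
                       config = pooling_config(model = "fixed"))
    b_both <- suppressWarnings(brute_force_meta_fragility(m, depth_cap = 6L))
    b_add <- suppressWarnings(brute_force_meta_fragility(m, depth_cap = 6L,
                                                         moves = "add-only"))
    if (b_both$converged && b_add$converged) {
      expect_lte(b_both$index, b_add$index)
    }
  }
})

test_that("the oracle reports an exhausted depth cap rather than failing
           silently", {
  # a strongly significant meta-analysis far more than 2 flips from the null
  m <- meta_analysis_spec(
    "deep", list(two_by_two_trial("A", 10, 400, 60, 400)),
    pooling_config(model = "fixed"))
  expect_warning(res <- brute_force_meta_fragility(m, depth_cap = 2L),
                 "depth cap")
  expect_false(res$converged)
  expect_true(is.na(res$index))
})

test_that("Walsh index grows roughly linearly in control-arm events", {
  # single trial, intervention events fixed; sweep the control events
  # over the significant range
  n <- 150L
  ev_t <- 5L
  idx <- c(); ev <- c()
  for (ec in 10:60) {
    tr <- two_by_two_trial("s", ev_t, n, ec, n)
    if (fisher_exact_two_sided(tr) >= 0.05) next
    r <- walsh_fragility(tr)
    if (!r$converged) next
    idx <- c(idx, r$index); ev <- c(ev, ec)
  }
  expect_gt(length(idx), 20)
  expect_true(all(diff(idx) >= 0))                 # monotone non-decreasing
  fit <- stats::lm(idx ~ ev)
  expect_gt(summary(fit)$r.squared, 0.9)           # close to linear
})

test_that("fragility index correlates negatively with the pooled p-value", {
  rep <- run_pipeline(corpus_model(n_meta = 60L, seed = 4242L))
  ok <- rep$meta[rep$meta$converged, ]
  expect_lt(stats::cor(ok$index, ok$p_value, method = "pearson"), 0)
  expect_lt(stats::cor(ok$index, ok$p_value, method = "spearman"), 0)
})

test_that("the two-study contrast penalises the small study", {
  ct <- construct_two_study_contrast()
  fi_small <- walsh_fragility(ct$small)$index
  fi_large <- walsh_fragility(ct$large)$index
  expect_equal(fi_small, 1L)   # frozen from the enumeration oracle
  expect_equal(fi_large, 4L)   # frozen from the enumeration oracle
  expect_lt(fi_small, fi_large)
})
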
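# Pooling engines: Mantel-Haenszel fixed effect, DerSimonian-Laird
# random effects, zero-cell policy, and the Wald significance
# equivalence.

test_that("a single-trial meta-analysis returns the trial effect", {
  m <- meta_analysis_spec("m", list(two_by_two_trial("A", 10, 100, 20, 100)),
                          pooling_config(model = "fixed"))
  res <- pool(m)
  expect_equal(exp(res$log_effect), 0.5, tolerance = 1e-12)
  expect_equal(res$k, 1L)
  expect_equal(res$tau2, 0)

  # the random model with one trial degenerates to the same estimate on
  # corrected-free counts (no zero cells here, so y is the plain log RR)
  mr <- meta_analysis_spec("m", m$trials, pooling_config(model = "random"))
  expect_equal(exp(pool(mr)$log_effect), 0.5, tolerance = 1e-12)
})

test_that("pooling duplicated evidence keeps the estimate, shrinks the se", {
  tr <- two_by_two_trial("A", 10, 100, 20, 100)
  one <- pool(meta_analysis_spec("m1", list(tr), pooling_config(model = "fixed")))
  tr2 <- tr; tr2$trial_id <- "B"
  both <- pool(meta_analysis_spec("m2", list(tr, tr2),
                                  pooling_config(model = "fixed")))
  expect_equal(both$log_effect, one$log_effect, tolerance = 1e-12)
  expect_lt(both$se, one$se)
})

test_that("three-trial fixture matches the metafor-frozen values", {
  # frozen from rma.mh(measure="RR", add=0, to="none", correct=FALSE) and
  # rma(measure="RR", method="DL", add=1/2, to="only0")
  fx <- pool(fixture_meta3("fixed"))
  expect_equal(fx$log_effect, -0.466925709013809, tolerance = 1e-10)
  expect_equal(fx$se, 0.174928040522155, tolerance = 1e-10)
  expect_equal(fx$q_stat, 0.956885621062584, tolerance = 1e-10)

  rx <- pool(fixture_meta3("random"))
  expect_equal(rx$log_effect, -0.464480344842839, tolerance = 1e-10)
  expect_equal(rx$se, 0.175554897471315, tolerance = 1e-10)
  expect_equal(rx$tau2, 0)
})

test_that("both engines agree with metafor on random meta-analyses", {
  library(metafor)
  set.seed(21)
  for (i in 1:25) {
    m <- rand_meta(k = sample(2:5, 1), max_arm = 80)
    cts <- metafragility:::.spec_counts(m)
    keep <- !(cts$a == 0 & cts$c == 0)
    if (sum(keep) < 2) next
    a <- cts$a[keep]; n1 <- cts$n1[keep]; cc <- cts$c[keep]; n2 <- cts$n2[keep]

    mine <- metafragility:::.pool_core(cts$a, cts$n1, cts$c, cts$n2,
                                       "rr", "fixed", 0.05)
    ref <- suppressWarnings(rma.mh(ai = a, n1i = n1, ci = cc, n2i = n2,
                                   measure = "RR", add = 0, to = "none",
                                   correct = FALSE))
    expect_equal(mine$log_effect, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)

    mine_dl <- metafragility:::.pool_core(cts$a, cts$n1, cts$c, cts$n2,
                                          "rr", "random", 0.05)
    ref_dl <- suppressWarnings(rma(ai = a, bi = n1 - a, ci = cc, di = n2 - cc,
                                   measure = "RR", method = "DL",
                                   add = 1 / 2, to = "only0"))
    expect_equal(mine_dl$log_effect, as.numeric(ref_dl$beta), tolerance = 1e-10)
    expect_equal(mine_dl$se, ref_dl$se, tolerance = 1e-10)
    expect_equal(mine_dl$tau2, ref_dl$tau2, tolerance = 1e-8)

    mine_or <- metafragility:::.pool_core(cts$a, cts$n1, cts$c, cts$n2,
                                          "or", "fixed", 0.05)
    ref_or <- suppressWarnings(rma.mh(ai = a, bi = n1 - a, ci = cc,
                                      di = n2 - cc, measure = "OR",
                                      add = 0, to = "none", correct = FALSE))
    expect_equal(mine_or$log_effect, as.numeric(ref_or$beta), tolerance = 1e-10)
    expect_equal(mine_or$se, ref_or$se, tolerance = 1e-10)
  }
})

test_that("tau2 is zero whenever Q <= k - 1, and the DL CI is never
           narrower than the inverse-variance fixed CI", {
  set.seed(22)
  for (i in 1:200) {
    m <- rand_meta(k = sample(2:4, 1), config = pooling_config(model = "random"))
    res <- tryCatch(pool(m), error = function(e) NULL)
    if (is.null(res)) next
    if (res$q_stat <= res$k - 1) expect_equal(res$tau2, 0)
    # inverse-variance fixed se from the same per-trial effects
    cts <- metafragility:::.spec_counts(m)
    keep <- !(cts$a == 0 & cts$c == 0)
    eff <- metafragility:::.trial_effects(cts$a[keep], cts$n1[keep],
                                          cts$c[keep], cts$n2[keep], "rr")
    se_iv <- sqrt(1 / sum(1 / eff$v))
    expect_gte(res$se, se_iv - 1e-12)
  }
})

test_that("CI excluding 1 is equivalent to p < alpha (Wald construction)", {
  set.seed(23)
  checked <- 0L
  for (i in 1:400) {
    cfg <- pooling_config(model = sample(c("fixed", "random"), 1),
                          alpha = sample(c(0.01, 0.05, 0.1), 1))
    m <- rand_meta(k = sample(1:4, 1), config = cfg,
                   rr_range = c(0.2, 1.6))
    res <- tryCatch(pool(m), error = function(e) NULL)
    if (is.null(res)) next
    checked <- checked + 1L
    expect_identical(is_significant(res), res$p_value < cfg$alpha)
  }
  expect_gt(checked, 300)
})

test_that("boundary conventions: an interval touching 1 includes the null", {
  mk <- function(lo, hi) structure(list(ci_low = lo, ci_high = hi),
                                   class = "pooled_result")
  expect_true(is_significant(mk(1.10, 2.50)))
  expect_false(is_significant(mk(0.90, 1.30)))
  expect_false(is_significant(mk(1.00, 1.80)))
})

test_that("zero-cell policy: double-zero trials drop out of the pool but
           stay in the sample size", {
  m <- meta_analysis_spec(
    "m",
    list(two_by_two_trial("A", 10, 100, 20, 100),
         two_by_two_trial("Z", 0, 50, 0, 50)),
    pooling_config(model = "fixed"))
  res <- pool(m)
  expect_equal(res$k, 1L)
  expect_equal(exp(res$log_effect), 0.5, tolerance = 1e-12)
  expect_equal(m$sample_size, 300L)

  allzero <- meta_analysis_spec(
    "z", list(two_by_two_trial("Z", 0, 50, 0, 50)), pooling_config())
  expect_error(pool(allzero), "inestimable")
})

test_that("single zero cells are handled without error in both models", {
  m <- meta_analysis_spec(
    "m",
    list(two_by_two_trial("A", 0, 60, 8, 60),
         two_by_two_trial("B", 2, 80, 9, 80)),
    pooling_config(model = "random"))
  res <- pool(m)
  expect_true(is.finite(res$log_effect) && is.finite(res$se))
  m2 <- meta_analysis_spec("m", m$trials, pooling_config(model = "fixed"))
  res2 <- pool(m2)
  expect_true(is.finite(res2$log_effect) && is.finite(res2$se))
  expect_true(res$ci_low <= exp(res$log_effect) &&
                exp(res$log_effect) <= res$ci_high)
})
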
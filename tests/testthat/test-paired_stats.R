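# Descriptives, paired differences, and the signed-rank test.

test_that("describe_values matches the stated conventions", {
  d <- describe_values(c(1, 2, 3, 4, 5))
  expect_equal(d[["mean"]], 3)
  expect_equal(d[["median"]], 3)
  expect_equal(d[["q25"]], 2)
  expect_equal(d[["q75"]], 4)

  one <- describe_values(7)
  expect_equal(unname(one), c(7, 0, 7, 7, 7))
  expect_error(describe_values(numeric(0)), "non-empty")
})

test_that("describe_values quantiles match the sort-and-interpolate oracle", {
  with_seed_t(7, x <- rnorm(1000))
  d <- describe_values(x)
  expect_equal(d[["q25"]], quantile7_oracle(x, 0.25), tolerance = 1e-12)
  expect_equal(d[["median"]], quantile7_oracle(x, 0.5), tolerance = 1e-12)
  expect_equal(d[["q75"]], quantile7_oracle(x, 0.75), tolerance = 1e-12)
})

test_that("paired_differences uses the stress-minus-rest sign convention", {
  feats <- data.frame(
    subject_id = c("a", "a", "b", "b"),
    session = c("rest", "stress", "rest", "stress"),
    SD2 = c(0.08, 0.05, 0.07, 0.07)
  )
  pd <- paired_differences(feats, "SD2")
  expect_equal(pd$differences, c(-0.03, 0))
  expect_identical(pd$subjects, c("a", "b"))

  same <- feats; same$SD2 <- rep(c(0.08, 0.08), 2)
  expect_true(all(paired_differences(same, "SD2")$differences == 0))

  broken <- feats[-2, ]
  expect_error(paired_differences(broken, "SD2"), "'a'")
  expect_error(paired_differences(feats, "nope"), "unknown feature")
})

test_that("signed-rank exact p-values: spec cases and enumeration oracle", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 2 / 2^6)
  expect_equal(w$statistic, 21)

  w2 <- wilcoxon_signed_rank(c(-1.5, 1.5, -2.2, 2.2))
  expect_equal(w2$p_value, 1)

  # zero differences are discarded before ranking
  w3 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(w3$n_effective, 3L)

  wz <- wilcoxon_signed_rank(rep(0, 8))
  expect_true(wz$degenerate)
  expect_equal(wz$p_value, 1)

  with_seed_t(61, {
    for (i in 1:20) {
      d <- round(rnorm(sample(5:12, 1)), 1)   # rounding induces ties/zeros
      d <- d[d != 0]
      if (length(d) < 5) next
      expect_equal(wilcoxon_signed_rank(d)$p_value, wsr_exact_oracle(d),
                   tolerance = 1e-12)
    }
  })
})

test_that("signed-rank p is symmetric under sign reversal and tracks wilcox.test", {
  with_seed_t(62, {
    for (i in 1:10) {
      d <- rnorm(10) + 0.5
      expect_equal(wilcoxon_signed_rank(d)$p_value,
                   wilcoxon_signed_rank(-d)$p_value, tolerance = 1e-12)
      # tie-free continuous data: R's exact signed-rank test is the same test
      expect_equal(wilcoxon_signed_rank(d)$p_value,
                   stats::wilcox.test(d, exact = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("exact and approximate branches agree near the crossover", {
  with_seed_t(63, {
    diffs <- replicate(50, rnorm(12, 0.3), simplify = FALSE)
  })
  for (d in diffs) {
    p_exact <- wilcoxon_signed_rank(d, exact_max = 12)$p_value
    p_approx <- wilcoxon_signed_rank(d, exact_max = 0)$p_value
    # the continuity-corrected normal approximation (identical to
    # wilcox.test's) genuinely deviates from the exact law by up to ~0.014
    # at n = 12, so 0.02 is the attainable agreement bound
    expect_lt(abs(p_exact - p_approx), 0.02)
    expect_equal(p_approx,
                 suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("summary tables have the 13-feature layout and display rule", {
  feats <- make_toy_features(10, stats::setNames(as.list(rep(0.5, 13)),
                                                 hrv_feature_names()), seed = 2)
  s3 <- session_summary_table(feats)
  expect_equal(s3$feature, hrv_feature_names())
  expect_true(all(c("rest_mean", "stress_q75") %in% names(s3)))
  s4 <- difference_table(feats)
  expect_equal(nrow(s4), 13)
  expect_true(all(s4$q25 <= s4$median & s4$median <= s4$q75))
  expect_true(all(s4$p_display[s4$p_value < 0.01] == "<0.01"))
})
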
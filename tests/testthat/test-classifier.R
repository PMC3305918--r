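# LDA rule, performance measures, subject-wise CV, exhaustive search.

test_that("1-D equal-variance LDA puts the boundary at the class-mean midpoint", {
  df <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:10), each = 2),
    session = rep(c("rest", "stress"), 10),
    x = rep(c(0, 10), 10) + rep(c(-1, 1), each = 2, length.out = 20)
  )  # both classes have within-class spread {-1, +1} about their means
  rule <- train_lda(df, subset = "x")
  expect_equal(-rule$intercept / rule$weights[["x"]], 5, tolerance = 1e-12)
  expect_identical(predict(rule, c(x = 6)), "stress")
  expect_identical(predict(rule, c(x = 4)), "rest")
})

test_that("duplicated feature triggers the ridge fallback but still separates", {
  df <- make_toy_features(12, list(f1 = 3), noise = 0.5, seed = 5)
  df$f2 <- df$f1
  expect_warning(rule <- train_lda(df, subset = c("f1", "f2")), "singular")
  expect_true(mean(predict(rule, df) == df$session) == 1)
})

test_that("LDA recovers the analytic Fisher direction on 2-D Gaussians", {
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  delta <- c(1, 0.5)
  L <- chol(Sigma)
  with_seed_t(3, {
    Z <- matrix(rnorm(2000 * 2), ncol = 2) %*% L
    y <- rep(c("rest", "stress"), each = 1000)
    Z[y == "stress", ] <- sweep(Z[y == "stress", ], 2, delta, "+")
  })
  rule <- train_lda(Z, subset = c("a", "b"), labels = y)
  w_true <- solve(Sigma, delta)
  expect_lt(angle_deg(rule$weights, w_true), 5)
})

test_that("rule convention: strict > 0 means stress, 0 is rest, negation flips", {
  rule <- structure(list(feature_names = c("SD1", "SD2", "En02"),
                         weights = c(SD1 = 203.99, SD2 = -108.74, En02 = -8.26),
                         intercept = 10.64),
                    class = "linear_rule")
  # a large-SD2 record drives the score negative -> rest
  expect_identical(predict(rule, c(SD1 = 0.02, SD2 = 0.20, En02 = 1.0)), "rest")
  # a record exactly on the boundary is rest
  x0 <- c(SD1 = 0.02, SD2 = 0.10, En02 = 1.0)
  x0[["En02"]] <- (10.64 + 203.99 * x0[["SD1"]] - 108.74 * x0[["SD2"]]) / 8.26
  expect_equal(rule_scores(rule, x0), 0, tolerance = 1e-12)
  expect_identical(predict(rule, x0), "rest")

  neg <- rule
  neg$weights <- -neg$weights; neg$intercept <- -neg$intercept
  x1 <- c(SD1 = 0.03, SD2 = 0.04, En02 = 0.9)
  expect_false(predict(rule, x1) == predict(neg, x1))
  expect_error(predict(rule, c(SD1 = 0.02, SD2 = 0.1)), "missing feature")
})

test_that("performance measures follow the confusion-matrix formulae", {
  perf <- classification_performance(rep(c("stress", "rest"), each = 2),
                                     rep(c("stress", "rest"), each = 2))
  expect_equal(as.numeric(perf), rep(1, 5))

  # counts consistent with a 90%/86%/95% classifier on 42 paired subjects
  truth <- c(rep("stress", 42), rep("rest", 42))
  pred <- c(rep("stress", 36), rep("rest", 6), rep("rest", 40), rep("stress", 2))
  perf2 <- classification_performance(truth, pred)
  expect_equal(unname(perf2["ACC"]), 76 / 84)
  expect_equal(unname(perf2["SEN"]), 36 / 42)
  expect_equal(unname(perf2["SPE"]), 40 / 42)
  expect_equal(unname(perf2["PPV"]), 36 / 38)
  expect_equal(unname(perf2["NPV"]), 40 / 46)

  all_rest <- classification_performance(truth, rep("rest", 84))
  expect_equal(unname(all_rest["SEN"]), 0)
  expect_true(is.na(all_rest["PPV"]))
  expect_identical(attr(all_rest, "undefined"), "PPV")
  expect_error(classification_performance("rest", c("rest", "rest")), "equal length")
})

test_that("subject folds are balanced, paired and deterministic", {
  subjects <- sprintf("S%02d", 1:42)
  f <- make_subject_folds(subjects, k = 10, seed = 99)
  expect_identical(sort(as.integer(table(f))), c(rep(4L, 8), rep(5L, 2)))
  expect_identical(f, make_subject_folds(subjects, k = 10, seed = 99))
  expect_false(identical(unname(f), unname(make_subject_folds(subjects, 10, 100))))
  expect_error(make_subject_folds(subjects[1:5], k = 10), "exceeds")

  # both records of a subject share a fold by construction
  df <- make_toy_features(12, list(f1 = 1), seed = 8)
  folds <- make_subject_folds(df, k = 4, seed = 1)
  rec_folds <- folds[df$subject_id]
  expect_true(all(tapply(rec_folds, df$subject_id, function(v) length(unique(v))) == 1))
})

test_that("cross-validation: separable data, ordering invariance, report shape", {
  df <- make_toy_features(16, list(f1 = 50, f2 = 0), noise = 0.5, seed = 9)
  folds <- make_subject_folds(df, k = 4, seed = 2)
  cv <- cross_validate(df, c("f1", "f2"), folds)
  expect_equal(cv$averages[["ACC"]], 1)
  expect_equal(nrow(cv$folds), 4)
  expect_true(all(cv$folds$TP + cv$folds$FN ==
                    tapply(df$session == "stress", folds[df$subject_id], sum)))

  # permuting subject rows leaves the averages unchanged (same fold assignment)
  perm <- order(rev(seq_len(nrow(df))))
  cv2 <- cross_validate(df[perm, ], c("f1", "f2"), folds)
  expect_equal(cv2$averages, cv$averages)
})

test_that("exhaustive search enumerates 2^p subsets and finds planted signal", {
  expect_length(enumerate_subsets(c("a", "b", "c")), 8)

  df <- make_toy_features(16, list(f1 = 0, f2 = 4, f3 = 0), noise = 0.5, seed = 10)
  folds <- make_subject_folds(df, k = 4, seed = 3)
  rank3 <- exhaustive_search(df, folds, feature_names = c("f1", "f2", "f3"))
  expect_equal(attr(rank3, "n_enumerated"), 8L)
  expect_equal(attr(rank3, "n_evaluated"), 7L)
  expect_equal(nrow(rank3), 7L)
  expect_true(grepl("f2", rank3$subset[1]))

  # the moment-based fast path must reproduce cross_validate exactly
  for (sub in list("f2", c("f1", "f3"), c("f1", "f2", "f3"))) {
    cv <- cross_validate(df, sub, folds)
    row <- rank3[rank3$subset == paste(sub, collapse = ","), ]
    expect_equal(row$ACC, cv$averages[["ACC"]], tolerance = 1e-12)
    expect_equal(row$SEN, cv$averages[["SEN"]], tolerance = 1e-12)
    expect_equal(row$NPV, cv$averages[["NPV"]], tolerance = 1e-12)
  }

  # reproducible ranking for a fixed fold assignment
  rank3b <- exhaustive_search(df, folds, feature_names = c("f1", "f2", "f3"))
  expect_identical(rank3, rank3b)
})

test_that("final_rule reduces single features to directed thresholds", {
  df <- data.frame(subject_id = rep(sprintf("S%d", 1:6), each = 2),
                   session = rep(c("rest", "stress"), 6),
                   f = rep(c(1, 0), 6))
  # zero within-class variance is inherently singular: the ridge path warns
  expect_warning(rule <- final_rule(df, "f"), "singular")
  expect_equal(rule$threshold, 0.5, tolerance = 1e-12)
  expect_identical(rule$direction, "<")

  df$g <- rep(c(0.2, 0.6), 6)  # stress mean above rest -> ">"
  expect_warning(rule_g <- final_rule(df, "g"), "singular")
  expect_identical(rule_g$direction, ">")
  expect_equal(rule_g$threshold, 0.4, tolerance = 1e-12)

  df$h <- df$f + rnorm(12, 0, 1e-3)
  rule3 <- suppressWarnings(final_rule(df, c("f", "g", "h")))
  expect_match(rule3$text, "> 0$")
  expect_length(rule3$weights, 3)
})
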
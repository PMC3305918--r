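# Synthetic paired-cohort generator.

test_that("parameter invariants are enforced", {
  expect_error(synthetic_params(ar_coeff_stress = 1), "AR coefficients")
  expect_error(synthetic_params(ectopic_rate = 0.15), "ectopic_rate")
  expect_error(synthetic_params(noise_sd_rest = -0.01), ">= 0")
  expect_error(synthetic_params(rest_mean_rr = 0), "positive")
})

test_that("degenerate generator yields a constant series of the expected length", {
  p <- synthetic_params(n_subjects = 1, lf_amplitude_rest = 0, hf_amplitude = 0,
                        noise_sd_rest = 0, ectopic_rate = 0,
                        between_subject_sd = 0, seed = 4)
  rr <- generate_session(p, 0, "rest")
  expect_true(all(rr$intervals == p$rest_mean_rr))
  expect_length(rr$intervals, ceiling(p$duration / p$rest_mean_rr))
  expect_true(all(rr$labels == "N"))
})

test_that("default sessions look like 5-minute physiologic records", {
  p <- synthetic_params(n_subjects = 1, seed = 1)
  rr <- generate_session(p, 0, "rest")
  expect_gt(length(rr$intervals), 300)
  expect_lt(length(rr$intervals), 420)
  expect_true(all(rr$intervals > 0.3 & rr$intervals < 1.5))
  expect_gte(sum(rr$intervals), p$duration)
})

test_that("generation is deterministic and subject streams are independent", {
  p <- synthetic_params(n_subjects = 6, seed = 5)
  a <- generate_session(p, 2, "stress")
  b <- generate_session(p, 2, "stress")
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$labels, b$labels)

  # a subject's record does not depend on how many subjects exist
  p3 <- synthetic_params(n_subjects = 3, seed = 5)
  c3 <- generate_cohort(p3)
  c6 <- generate_cohort(p)
  for (i in 1:6) expect_identical(c3[[i]]$intervals, c6[[i]]$intervals)

  # different sessions and subjects differ
  expect_false(identical(generate_session(p, 2, "rest")$intervals, a$intervals))
  expect_false(identical(generate_session(p, 3, "stress")$intervals, a$intervals))
})

test_that("cohorts are paired and hit the nominal rest mean RR within 2%", {
  p <- synthetic_params(n_subjects = 20, seed = 6)
  cohort <- generate_cohort(p)
  expect_length(cohort, 40)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  ses <- vapply(cohort, `[[`, "", "session")
  expect_true(all(table(ids) == 2))
  expect_true(all(tapply(ses, ids, function(s) setequal(s, c("rest", "stress")))))

  rest_means <- vapply(cohort[ses == "rest"],
                       function(r) mean(r$intervals), numeric(1))
  expect_lt(abs(mean(rest_means) - p$rest_mean_rr) / p$rest_mean_rr, 0.02)
})

test_that("cohort round-trips through the on-disk format", {
  p <- synthetic_params(n_subjects = 2, seed = 8, duration = 60)
  cohort <- generate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_length(back, 4)
  i <- which(vapply(back, `[[`, "", "subject_id") == "S01" &
               vapply(back, `[[`, "", "session") == "stress")
  j <- which(vapply(cohort, `[[`, "", "subject_id") == "S01" &
               vapply(cohort, `[[`, "", "session") == "stress")
  expect_identical(back[[i]]$intervals, cohort[[j]]$intervals)
  expect_identical(back[[i]]$labels, cohort[[j]]$labels)
})

test_that("heavily ectopic records fail the reliability criterion", {
  # negative-path fixture for the 90% NN/RR filter: 15% non-normal beats
  with_seed_t(9, labels <- ifelse(runif(300) < 0.15, "V", "N"))
  rr <- rr_series(rep(c(0.8, 0.85), 150), labels)
  expect_false(reliability_check(to_nn(rr)))
})
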
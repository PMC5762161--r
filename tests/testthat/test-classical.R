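test_that("naive pooled t-test reproduces the printed observation-level analysis", {
  tt <- pooled_t_test(lymph_size)
  expect_equal(tt$difference, 0.283, tolerance = 2e-3)
  expect_equal(tt$statistic, 2.501, tolerance = 5e-4)
  expect_equal(tt$df, 70L)
  expect_equal(tt$conf.int, c(0.057, 0.508), tolerance = 2e-3)
  expect_equal(tt$p.value, 0.015, tolerance = 2e-2)
})

test_that("pooled t-test matches hand-computed and degenerate cases", {
  # {1,2,3} vs {4,5,6}: d = -3, pooled s2 = 1, sed = sqrt(2/3)
  tt <- pooled_t_test(tibble::tibble(group = rep(c("a", "b"), each = 3),
                                     value = c(1, 2, 3, 4, 5, 6)))
  expect_equal(tt$difference, -3)
  expect_equal(tt$pooled_s2, 1)
  expect_equal(tt$sed, sqrt(2 / 3))
  expect_equal(abs(tt$statistic), 3.674, tolerance = 5e-4)

  sym <- pooled_t_test(tibble::tibble(group = rep(c("a", "b"), each = 3),
                                      value = c(1, 2, 3, 1, 2, 3)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)

  expect_error(pooled_t_test(tibble::tibble(group = "a", value = 1:3)),
               "two groups")
  expect_error(pooled_t_test(tibble::tibble(group = rep(c("a", "b"), each = 2),
                                            value = c(1, 1, 1, 1))),
               "undefined")
})

test_that("pooled t-test agrees with the textbook oracle on random datasets", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
      x1 <- rnorm(n1, sd = runif(1, 0.5, 2)); x2 <- rnorm(n2, 1)
      tt <- pooled_t_test(tibble::tibble(group = rep(c("a", "b"), c(n1, n2)),
                                         value = c(x1, x2)))
      expect_ttest_equal(tt, t_oracle(x1, x2))
    }
  })
})

test_that("subject summaries reproduce the printed per-subject means", {
  s <- subject_summaries(lymph_size)
  expect_equal(nrow(s), 12L)
  expect_equal(round(s$value[order(as.integer(s$subject))], 2),
               c(1.85, 2.78, 1.79, 2.24, 3.15, 2.60, 2.42, 1.57, 1.82, 2.26,
                 2.02, 2.62))
  # single-record subjects: summary equals the record
  one <- as_nested_data(tibble::tibble(group = rep(c("a", "b"), each = 2),
                                       subject = as.character(1:4),
                                       value = c(5, 6, 7, 8)))
  expect_equal(subject_summaries(one)$value, c(5, 6, 7, 8))
  # unbalanced data still yield one value per subject, with a warning
  expect_warning(s2 <- subject_summaries(remove_fraction(lymph_size, 0.5, 7)),
                 "unweighted")
  expect_equal(nrow(s2), 12L)
})

test_that("subject-based t-test reproduces the printed subject-level analysis", {
  tt <- subject_based_t_test(lymph_size)
  expect_equal(tt$statistic, 1.043, tolerance = 5e-4)
  expect_equal(tt$df, 10L)
  expect_equal(tt$conf.int, c(-0.321, 0.886), tolerance = 2e-3)
  # balanced design: group means identical to the naive analysis
  naive <- pooled_t_test(lymph_size)
  expect_equal(tt$means, naive$means)
  expect_equal(tt$difference, naive$difference)
  # positive within-subject correlation: wider sed than naive
  expect_gt(tt$sed, naive$sed)
})

test_that("subject-based t-test collapses to the pooled test with one record per subject", {
  d <- as_nested_data(tibble::tibble(group = rep(c("a", "b"), each = 4),
                                     subject = as.character(1:8),
                                     value = c(rnorm(4), rnorm(4, 1))))
  expect_ttest_equal(subject_based_t_test(d), pooled_t_test(d))
})

test_that("2x2 odds ratio matches the printed naive analysis and the direct formula", {
  or <- odds_ratio_2x2(43, 82, 79, 46)
  expect_equal(round(or$or, 2), 0.31)
  expect_equal(or$se_log_or, sqrt(1 / 43 + 1 / 82 + 1 / 79 + 1 / 46))

  expect_equal(odds_ratio_2x2(7, 13, 7, 13)$or, 1)
  unit <- odds_ratio_2x2(1, 1, 1, 1)
  expect_equal(unit$or, 1)
  expect_equal(unit$se_log_or, 2)
  expect_error(odds_ratio_2x2(0, 5, 3, 2), "zero cell")
  expect_gt(odds_ratio_2x2(0, 5, 3, 2, correction = TRUE)$or, 0)
})

test_that("IRLS logistic regression reproduces the printed naive binomial analysis", {
  g <- fit_logistic_glm(lymph_count)
  expect_equal(round(g$or_table$or, 2), 0.31)
  expect_equal(g$or_table$conf.low, 0.18, tolerance = 2e-2)
  expect_equal(g$or_table$conf.high, 0.51, tolerance = 2e-2)
  expect_equal(g$coefficients$std.error[2], 0.264, tolerance = 5e-3)
  expect_true(g$converged)
})

test_that("logistic GLM on the group-saturated model equals the 2x2 odds ratio", {
  g <- fit_logistic_glm(lymph_count, reference = "None")
  or <- odds_ratio_2x2(43, 125 - 43, 79, 125 - 79)
  expect_equal(g$coefficients$estimate[2], or$log_or, tolerance = 1e-10)
  expect_equal(g$coefficients$std.error[2], or$se_log_or, tolerance = 1e-10)
})

test_that("IRLS agrees with stats::glm and recovers known coefficients", {
  ref <- stats::glm(cbind(events, trials - events) ~ group,
                    family = binomial, data = lymph_count)
  g <- fit_logistic_glm(lymph_count)
  expect_equal(g$coefficients$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(g$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)

  # parameter recovery at large n
  withr::with_seed(99, {
    n_subj <- 400L
    grp <- rep(c("A", "B"), each = n_subj / 2)
    p <- plogis(0.4 - 0.9 * (grp == "B"))
    sim <- as_nested_data(tibble::tibble(
      group = grp, subject = as.character(seq_len(n_subj)),
      events = rbinom(n_subj, 20L, p), trials = 20L), "binomial")
  })
  gs <- fit_logistic_glm(sim)
  expect_equal(gs$coefficients$estimate[1], 0.4,
               tolerance = 4 * gs$coefficients$std.error[1])
  expect_equal(gs$coefficients$estimate[2], -0.9,
               tolerance = 4 * gs$coefficients$std.error[2])
})
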
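fit_full <- fit_nested_lmm(lymph_size)
fit_subj <- fit_nested_lmm(lymph_size, levels = "subject")

test_that("REML fit of the size data reproduces the printed variance components", {
  comp <- setNames(fit_full$components$sd, fit_full$components$level)
  expect_equal(unname(comp["subject"]), 0.436, tolerance = 1e-3 / 0.436)
  expect_equal(unname(comp["residual"]), 0.122, tolerance = 1e-3 / 0.122)
  # printed "0.236" is inconsistent with its own printed CI (0.151-0.362);
  # the REML optimum, confirmed by two independent implementations, is 0.2336
  expect_equal(unname(comp["sample"]), 0.2336, tolerance = 1e-3 / 0.2336)
  expect_equal(icc(fit_full), 0.733, tolerance = 0.01 / 0.733)
  # variance ratios: subjects vs samples ~3.5x, subjects vs slices ~13x
  expect_equal(comp[["subject"]]^2 / comp[["sample"]]^2, 3.5, tolerance = 0.05)
  expect_equal(comp[["subject"]]^2 / comp[["residual"]]^2, 13, tolerance = 0.05)
})

test_that("REML fixed-effect inference uses the between-subject stratum", {
  fit <- fit_nested_lmm(lymph_size, reference = "Short RT")
  fx <- fit$fixed[fit$fixed$term == "groupNone", ]
  expect_equal(fx$estimate, 0.283, tolerance = 2e-3)
  expect_equal(fx$df, 10L)
  expect_equal(fx$statistic, 1.043, tolerance = 5e-4)
  expect_equal(c(fx$conf.low, fx$conf.high), c(-0.321, 0.886), tolerance = 2e-3)
  expect_equal(fx$p.value, 0.322, tolerance = 2e-3)
})

test_that("REML solution matches an independent mixed-model implementation", {
  d <- as.data.frame(lymph_size)
  d$samp <- interaction(d$subject, d$sample)
  ref <- lme4::lmer(value ~ group + (1 | subject) + (1 | samp), data = d,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit_full$components$sd,
               vc$sdcor[match(c("subject", "samp", "Residual"), vc$grp)],
               tolerance = 1e-4)
  expect_equal(fit_full$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit_full$fixed$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-5)
  ref0 <- lme4::lmer(value ~ group + (1 | subject), data = d, REML = TRUE)
  expect_equal(fit_subj$loglik, as.numeric(logLik(ref0)), tolerance = 1e-6)
})

test_that("variance-component intervals approximate the printed Wald-on-log CIs", {
  comp <- fit_full$components
  printed <- list(subject = c(0.262, 0.727), sample = c(0.151, 0.362),
                  residual = c(0.100, 0.149))
  for (lv in names(printed)) {
    row <- comp[comp$level == lv, ]
    expect_equal(c(row$conf.low, row$conf.high), printed[[lv]],
                 tolerance = 0.15)
  }
})

test_that("REML equals the ANOVA expected-mean-squares oracle on balanced data", {
  for (seed in c(11, 23, 37)) {
    d <- simulate_nested_dataset(example1_layout, 0.3, std_components, seed)
    mom <- anova_mom_oracle(d)
    if (any(mom <= 0)) next  # oracle outside the parameter space
    fit <- fit_nested_lmm(d, component_ci = FALSE)
    expect_equal(setNames(fit$components$variance, fit$components$level),
                 mom, tolerance = 1e-4)
  }
})

test_that("REML log-likelihood at the optimum beats the method-of-moments start", {
  prep <- uoa:::lmm_prepare(lymph_size, has_sample = TRUE, reference = NULL)
  start <- uoa:::lmm_start(prep, has_sample = TRUE)
  ll_start <- -0.5 * uoa:::lmm_profiled_neg2(start$gamma, prep, reml = TRUE)$neg2
  expect_gte(fit_full$loglik, ll_start)
})

test_that("LMM inference coincides exactly with the subject-based t-test on balanced data", {
  for (seed in 1:20) {
    d <- simulate_nested_dataset(example1_layout, 0.2, std_components, seed)
    tt <- subject_based_t_test(d)  # difference is G1 - G2
    fit <- fit_nested_lmm(d, reference = "G2", component_ci = FALSE)
    fx <- fit$fixed[fit$fixed$term == "groupG1", ]
    expect_equal(fx$estimate, tt$difference, tolerance = 1e-6)
    expect_equal(fx$std.error, tt$sed, tolerance = 1e-6)
    expect_equal(fx$statistic, tt$statistic, tolerance = 1e-6)
    expect_equal(fx$df, tt$df)
    expect_equal(c(fx$conf.low, fx$conf.high), tt$conf.int, tolerance = 1e-6)
  }
})

test_that("icc handles fits, component vectors, and degenerate inputs", {
  expect_equal(icc(c(subject = 0, sample = 1, residual = 1)), 0)
  expect_equal(icc(c(subject = 2, sample = 0, residual = 0)), 1)
  expect_equal(icc(c(subject = 3, sample = 4, residual = 0)), 9 / 25)
  expect_error(icc(c(subject = 0, residual = 0)), "undefined")
  expect_error(icc(fit_full, level = "slice"), "unknown level")
})

test_that("LRT between random structures reproduces the printed comparison", {
  lrt <- lrt_random_structure(fit_full, fit_subj)
  expect_equal(lrt$statistic, 39.92, tolerance = 0.05 / 39.92)
  expect_equal(lrt$df, 1L)
  expect_lt(lrt$p.value, 0.001)
  expect_lt(lrt$p.boundary, lrt$p.value + 1e-12)

  same <- lrt_random_structure(fit_full, fit_full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  other <- fit_nested_lmm(lymph_size, levels = "subject", reference = "Short RT")
  expect_error(lrt_random_structure(fit_full, other), "fixed effects differ")
  ml <- fit_nested_lmm(lymph_size, levels = "subject", method = "ML")
  expect_error(lrt_random_structure(fit_full, ml), "estimation methods")
})

test_that("LRT for a null sample effect rejects at or below the nominal rate", {
  null_comp <- c(subject = 0.4, sample = 0, residual = 0.2)
  rej <- withr::with_seed(17, {
    vapply(sample.int(1e6, 120), function(s) {
      d <- simulate_nested_dataset(example1_layout, 0, null_comp, s)
      full <- suppressWarnings(fit_nested_lmm(d, component_ci = FALSE))
      red <- fit_nested_lmm(d, levels = "subject", component_ci = FALSE)
      lrt_random_structure(full, red)$p.value < 0.05
    }, TRUE)
  })
  # boundary null: naive chi-squared(1) reference is conservative
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / length(rej)))
})

test_that("diagnostics return per-subject summaries and calibrated Q-Q pairs", {
  diag <- lmm_diagnostics(fit_full)
  expect_equal(nrow(diag$by_subject), 12L)
  expect_equal(nrow(diag$residuals), 72L)
  expect_equal(nrow(diag$qq), 72L)
  # residual identity: observed - fitted, record by record
  md <- fit_full$model_data
  expect_equal(md$residual, md$value - md$fitted, tolerance = 1e-12)
  # well-specified model: Q-Q pairs hug the identity
  d <- simulate_nested_dataset(design_layout(2, 12, 2, 6), 0, std_components, 5)
  qq <- lmm_diagnostics(fit_nested_lmm(d, component_ci = FALSE))$qq
  expect_gt(cor(qq$observed, qq$theoretical), 0.99)
  expect_lt(abs(coef(lm(observed ~ theoretical, qq))[2] - 1), 0.25)
})

test_that("unbalanced data fit cleanly and break the subject-summary equivalence", {
  d <- remove_fraction(lymph_size, 0.5, seed = 4)
  fit <- suppressWarnings(fit_nested_lmm(d, reference = "Short RT"))
  expect_true(fit$converged)
  expect_true(all(fit$components$sd > 0))
  expect_true(all(is.finite(fit$components$sd)))
  tt <- suppressWarnings(subject_based_t_test(d))
  fx <- fit$fixed[fit$fixed$term == "groupNone", ]
  expect_gt(abs(fx$estimate - tt$difference), 1e-4)
})

test_that("boundary variance components are flagged, not fatal", {
  # both sample means within every subject exactly equal: the sample-level
  # mean square is zero, so sigma_S must sit on the boundary
  d <- as_nested_data(tibble::tibble(
    group = rep(c("a", "b"), each = 18),
    subject = rep(as.character(1:6), each = 6),
    sample = rep(rep(c("1", "2"), each = 3), 6),
    replicate = rep(as.character(1:3), 12),
    value = rep(c(1, 2.5, 2, 4, 3.2, 5), each = 6) +
      rep(c(-0.2, 0, 0.2), 12)))
  fit <- suppressWarnings(fit_nested_lmm(d))
  comp <- setNames(fit$components$sd, fit$components$level)
  bnd <- setNames(fit$components$boundary, fit$components$level)
  expect_true(bnd[["sample"]])
  expect_lt(comp[["sample"]], 1e-3)
  expect_warning(fit_nested_lmm(d), "boundary")
})

test_that("tidy and glance expose the fit in broom style", {
  td <- tidy(fit_full)
  expect_true(all(c("effect", "term", "estimate", "conf.low") %in% names(td)))
  expect_equal(nrow(td), 5L)  # 2 fixed terms + 3 variance components
  gl <- glance(fit_full)
  expect_equal(gl$nobs, 72L)
  expect_true(gl$converged)
})
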
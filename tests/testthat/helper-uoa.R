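# Shared fixtures and independent oracles used across the test files.

lymph_size <- load_fixture("lymph_size")
lymph_count <- load_fixture("lymph_count")

std_components <- c(subject = 0.4, sample = 0.2, residual = 0.1)
example1_layout <- design_layout(n_groups = 2, subjects_per_group = 6,
                                 samples_per_subject = 2,
                                 replicates_per_sample = 3)

# Independent ANOVA expected-mean-squares oracle for a balanced
# subject/sample/replicate design, from the nested sums of squares:
# sigma_e^2 = MS_resid, sigma_S^2 = (MS_sample - MS_resid)/r,
# sigma_P^2 = (MS_subject - MS_sample)/(r*s).
anova_mom_oracle <- function(data) {
  d <- as.data.frame(data)
  d$samp <- paste(d$subject, d$sample)
  r <- length(unique(d$replicate))
  s <- length(unique(d$sample))
  grp_mean <- ave(d$value, d$group)
  subj_mean <- ave(d$value, d$subject)
  samp_mean <- ave(d$value, d$samp)
  n_grp <- length(unique(d$group))
  n_subj <- length(unique(d$subject))
  n_samp <- length(unique(d$samp))
  ms_subject <- sum((subj_mean - grp_mean)^2) / (n_subj - n_grp)
  ms_sample <- sum((samp_mean - subj_mean)^2) / (n_samp - n_subj)
  ms_resid <- sum((d$value - samp_mean)^2) / (nrow(d) - n_samp)
  c(subject = (ms_subject - ms_sample) / (r * s),
    sample = (ms_sample - ms_resid) / r,
    residual = ms_resid)
}

# Textbook pooled two-sample t oracle, written independently of the package.
t_oracle <- function(x1, x2, conf_level = 0.95) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  sed <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(x1) - mean(x2)
  tt <- d / sed
  df <- n1 + n2 - 2
  list(difference = d, sed = sed, statistic = tt, df = df,
       p.value = 2 * pt(-abs(tt), df),
       conf.int = d + c(-1, 1) * qt(1 - (1 - conf_level) / 2, df) * sed)
}

expect_ttest_equal <- function(a, b, tol = 1e-10) {
  expect_equal(a$difference, b$difference, tolerance = tol)
  expect_equal(a$statistic, b$statistic, tolerance = tol)
  expect_equal(a$df, b$df)
  expect_equal(a$p.value, b$p.value, tolerance = tol)
  expect_equal(a$conf.int, b$conf.int, tolerance = tol)
}
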
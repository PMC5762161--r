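#' Naive pooled two-sample t-test
#'
#' The observation-level ("naive") analysis: a pooled-variance two-sample
#' t-test that treats every row of the dataset as an independent
#' observation. With `d` the difference in group means, the pooled variance
#' is `s^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, the standard
#' error of the difference `sed = s * sqrt(1/n1 + 1/n2)`, and `t = d / sed`
#' on `n1 + n2 - 2` degrees of freedom. When rows are correlated within
#' subjects this test pseudoreplicates and its p-value is anti-conservative;
#' compare [subject_based_t_test()] and [fit_nested_lmm()].
#'
#' @param data A data frame with a `group` column and a `value` column
#'   (e.g. a continuous `nested_df`).
#' @param conf_level Confidence level for the interval on the difference.
#' @param reference Group label to list first; the reported difference is
#'   reference minus the other group. Default: first in sort order.
#' @return A `uoa_ttest` object; see [tidy.uoa_ttest()].
#' @examples
#' pooled_t_test(load_fixture("lymph_size"))
#' @export
pooled_t_test <- function(data, conf_level = 0.95, reference = NULL) {
  two_group_t(data$value, data$group, conf_level, reference, mode = "naive")
}

two_group_t <- function(values, groups, conf_level, reference, mode) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) {
    abort(sprintf("exactly two groups required, found %d", length(lev)))
  }
  if (!is.null(reference)) {
    if (!reference %in% lev) abort(sprintf("unknown reference group '%s'", reference))
    lev <- c(reference, setdiff(lev, reference))
  }
  x1 <- values[groups == lev[1]]
  x2 <- values[groups == lev[2]]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) abort("each group needs at least 2 observations")
  m1 <- mean(x1); m2 <- mean(x2)
  s1 <- var(x1); s2 <- var(x2)
  pooled <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  d <- m1 - m2
  if (pooled <= 0) {
    if (d == 0) abort("zero pooled variance and zero difference: t undefined")
    sed <- 0; tstat <- Inf * sign(d); p <- 0
  } else {
    sed <- sqrt(pooled) * sqrt(1 / n1 + 1 / n2)
    tstat <- d / sed
    p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  }
  df <- as.integer(n1 + n2 - 2)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  structure(list(
    groups = lev, means = setNames(c(m1, m2), lev), n = setNames(c(n1, n2), lev),
    s2 = setNames(c(s1, s2), lev), pooled_s2 = pooled,
    difference = d, sed = sed, statistic = tstat, df = df, p.value = p,
    conf.int = c(d - tcrit * sed, d + tcrit * sed), conf.level = conf_level,
    mode = mode
  ), class = "uoa_ttest")
}

#' @export
print.uoa_ttest <- function(x, ...) {
  cat(sprintf("%s two-sample t-test (pooled variance)\n",
              if (x$mode == "naive") "Naive observation-level" else "Subject-based"))
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  cat(sprintf("  means: %.4f vs %.4f, difference = %.4f (sed %.4f)\n",
              x$means[1], x$means[2], x$difference, x$sed))
  cat(sprintf("  t = %.3f on %d df, p = %.4g, %g%% CI (%.3f, %.3f)\n",
              x$statistic, x$df, x$p.value, 100 * x$conf.level,
              x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

#' @rdname pooled_t_test
#' @param x A `uoa_ttest`.
#' @param ... Unused.
#' @export
tidy.uoa_ttest <- function(x, ...) {
  tibble(
    estimate = x$difference, estimate1 = unname(x$means[1]),
    estimate2 = unname(x$means[2]), statistic = x$statistic,
    p.value = x$p.value, parameter = x$df,
    conf.low = x$conf.int[1], conf.high = x$conf.int[2],
    method = paste0(x$mode, " pooled t-test")
  )
}

#' @rdname pooled_t_test
#' @export
glance.uoa_ttest <- function(x, ...) tidy(x)

#' Per-subject summary measures
#'
#' Collapses a continuous nested dataset to one summary value per subject
#' (the experimental unit). Only the mean is currently available; when the
#' design is unbalanced the per-subject means average over unequal record
#' counts and a warning notes that they are unweighted (and so carry unequal
#' precision).
#'
#' @param data A continuous `nested_df`.
#' @param statistic Summary statistic; only `"mean"` is implemented.
#' @return A tibble with columns `group`, `subject`, `n_obs`, `value`.
#' @examples
#' subject_summaries(load_fixture("lymph_size"))
#' @export
subject_summaries <- function(data, statistic = "mean") {
  stopifnot(inherits(data, "nested_df"))
  if (outcome_kind(data) != "continuous") abort("continuous outcome required")
  statistic <- arg_match0(statistic, "mean")
  out <- data %>%
    group_by(.data$group, .data$subject) %>%
    summarise(n_obs = n(), value = mean(.data$value), .groups = "drop") %>%
    arrange(.data$group, .data$subject)
  if (n_distinct(out$n_obs) > 1L) {
    warn("unbalanced design: per-subject means are unweighted and have unequal precision")
  }
  out
}

#' Subject-based t-test
#'
#' The subject-summary analysis: collapse to one mean per subject with
#' [subject_summaries()], then run the pooled two-sample t-test on the
#' subject means. Between-subject variability alone assesses the treatment,
#' which is valid for a subject-level intervention (at some loss of
#' efficiency, and exactly equivalent to the nested mixed model on balanced
#' designs).
#'
#' @inheritParams pooled_t_test
#' @param data A continuous `nested_df`.
#' @return A `uoa_ttest` object.
#' @examples
#' subject_based_t_test(load_fixture("lymph_size"))
#' @export
subject_based_t_test <- function(data, conf_level = 0.95, reference = NULL) {
  s <- subject_summaries(data)
  two_group_t(s$value, s$group, conf_level, reference, mode = "subject")
}

#' Odds ratio from a 2x2 table
#'
#' `or = (events_a / nonevents_a) / (events_b / nonevents_b)`, with a Wald
#' interval on the log scale using
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. Group "a" is the numerator.
#'
#' @param events_a,nonevents_a Event and non-event counts in the numerator
#'   group.
#' @param events_b,nonevents_b Counts in the denominator (reference) group.
#' @param conf_level Confidence level.
#' @param correction Add 0.5 to every cell (only needed when a cell is 0);
#'   off by default.
#' @return A `uoa_or` object with fields `or`, `log_or`, `se_log_or`, `ci`,
#'   `counts`.
#' @examples
#' odds_ratio_2x2(43, 82, 79, 46)
#' @export
odds_ratio_2x2 <- function(events_a, nonevents_a, events_b, nonevents_b,
                           conf_level = 0.95, correction = FALSE) {
  counts <- c(events_a, nonevents_a, events_b, nonevents_b)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts == 0) && !correction) {
    abort("zero cell: use correction = TRUE for a 0.5 continuity correction")
  }
  if (correction) counts <- counts + 0.5
  log_or <- log(counts[1] / counts[2]) - log(counts[3] / counts[4])
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    or = exp(log_or), log_or = log_or, se_log_or = se,
    ci = exp(log_or + c(-z, z) * se), conf.level = conf_level,
    counts = matrix(c(events_a, nonevents_a, events_b, nonevents_b), 2,
                    byrow = TRUE, dimnames = list(c("a", "b"), c("events", "nonevents")))
  ), class = "uoa_or")
}

#' @export
print.uoa_or <- function(x, ...) {
  cat(sprintf("odds ratio = %.4f, log OR = %.4f (se %.4f), %g%% CI (%.3f, %.3f)\n",
              x$or, x$log_or, x$se_log_or, 100 * x$conf.level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @rdname odds_ratio_2x2
#' @param x A `uoa_or`.
#' @param ... Unused.
#' @export
tidy.uoa_or <- function(x, ...) {
  tibble(estimate = x$or, log_or = x$log_or, std.error = x$se_log_or,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' Conventional logistic regression (naive binomial analysis)
#'
#' Maximum-likelihood logistic regression of aggregated binomial outcomes
#' (`events` of `trials` per row) on the treatment group, fitted by
#' iteratively reweighted least squares. Every row is treated as
#' independent, so with repeat samples per subject this is the binomial
#' analogue of the naive t-test: the standard error of the log odds ratio
#' is understated when counts cluster within subjects (compare
#' [fit_logistic_glmm()]).
#'
#' Convergence: relative log-likelihood change below 1e-10, at most 100
#' iterations. Complete separation is detected (diverging coefficients) and
#' reported as an error.
#'
#' @param data A binomial `nested_df` with two groups.
#' @param conf_level Confidence level for Wald intervals.
#' @param reference Reference (baseline) group; default first in sort
#'   order. The reported odds ratio is for the non-reference group.
#' @return A `uoa_glm` object: `coefficients` tibble (log-odds scale),
#'   `or_table`, `loglik`, `deviance`, `vcov`, `converged`, `n_iter`.
#' @examples
#' fit_logistic_glm(load_fixture("lymph_count"))
#' @export
fit_logistic_glm <- function(data, conf_level = 0.95, reference = NULL) {
  stopifnot(inherits(data, "nested_df"))
  if (outcome_kind(data) != "binomial") abort("binomial outcome required")
  lev <- sort(unique(data$group))
  if (length(lev) != 2L) abort("exactly two groups required")
  if (!is.null(reference)) lev <- c(reference, setdiff(lev, reference))
  g <- factor(data$group, levels = lev)
  X <- model.matrix(~g)
  colnames(X) <- c("(Intercept)", paste0("group", lev[2]))
  k <- data$events; n <- data$trials
  y <- k / n

  beta <- c(qlogis((sum(k) + 0.5) / (sum(n) + 1)), 0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- n * mu * (1 - mu)
    if (any(w < 1e-12)) abort("complete separation detected: fitted probabilities at 0/1")
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    if (max(abs(beta)) > 30) abort("complete separation detected: coefficients diverging")
    ll <- sum(dbinom(k, n, plogis(drop(X %*% beta)), log = TRUE))
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-10 * (abs(ll) + 1e-10)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  if (!converged) warn("IRLS did not converge in 100 iterations")
  eta <- drop(X %*% beta); mu <- plogis(eta)
  vcov <- solve(t(X * (n * mu * (1 - mu))) %*% X)
  se <- sqrt(diag(vcov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  zstat <- beta / se
  coefs <- tibble(
    term = colnames(X), estimate = unname(beta), std.error = unname(se),
    statistic = unname(zstat), p.value = 2 * pnorm(-abs(unname(zstat))),
    conf.low = unname(beta - zq * se), conf.high = unname(beta + zq * se)
  )
  ll_sat <- sum(dbinom(k, n, ifelse(k == 0 | k == n, k / n, k / n), log = TRUE))
  structure(list(
    coefficients = coefs,
    or_table = tibble(term = coefs$term[-1], or = exp(coefs$estimate[-1]),
                      conf.low = exp(coefs$conf.low[-1]),
                      conf.high = exp(coefs$conf.high[-1])),
    loglik = ll_old, deviance = 2 * (ll_sat - ll_old), vcov = vcov,
    converged = converged, n_iter = it, reference = lev[1], groups = lev,
    conf.level = conf_level
  ), class = "uoa_glm")
}

#' @export
print.uoa_glm <- function(x, ...) {
  cat(sprintf("Logistic regression (naive, IRLS; reference group '%s')\n", x$reference))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("OR(%s) = %.4f, %g%% CI (%.3f, %.3f); loglik %.3f\n",
              x$or_table$term[1], x$or_table$or[1], 100 * x$conf.level,
              x$or_table$conf.low[1], x$or_table$conf.high[1], x$loglik))
  invisible(x)
}

#' @rdname fit_logistic_glm
#' @param x A `uoa_glm`.
#' @param ... Unused.
#' @export
tidy.uoa_glm <- function(x, ...) x$coefficients

#' @rdname fit_logistic_glm
#' @export
glance.uoa_glm <- function(x, ...) {
  tibble(logLik = x$loglik, deviance = x$deviance,
         converged = x$converged, n_iter = x$n_iter)
}
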
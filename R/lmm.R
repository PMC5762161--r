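#' Fit a nested Gaussian linear mixed model by REML
#'
#' Fits `y = X beta + b_subject + b_sample + e` with independent Gaussian
#' random intercepts for each nesting level (`b_subject ~ N(0, sigma_P^2)`,
#' `b_sample ~ N(0, sigma_S^2)` for samples within subjects) and residual
#' `e ~ N(0, sigma_e^2)`, by restricted maximum likelihood (or ML). The
#' fixed part is the treatment group. This is the correct analysis when
#' treatment is applied at the subject level but multiple samples and
#' replicate slices are measured per subject: the between-subject stratum,
#' not the pooled observation-level variance, assesses the treatment.
#'
#' Estimation profiles `beta` and the residual variance out of the
#' (restricted) likelihood in closed form, leaving an optimisation over the
#' log variance ratios `log(sigma_level^2 / sigma_e^2)`, started at
#' ANOVA method-of-moments values and solved by L-BFGS-B. All linear
#' algebra works block-wise per subject (the marginal covariance is block
#' diagonal), with Cholesky factors cached per within-subject design
#' pattern, and is exact.
#'
#' Inference for the fixed treatment effect uses containment (stratum)
#' degrees of freedom: a subject-level treatment is tested against the
#' between-subject stratum, `df = n_subjects - n_groups`, so on a balanced
#' design the result coincides exactly with [subject_based_t_test()].
#' Confidence intervals for the standard deviations are Wald intervals on
#' the log(sigma) scale from the numerically differentiated REML Hessian.
#' A variance ratio driven to the optimiser boundary is reported as
#' essentially zero with a `boundary` flag (inference then effectively
#' degrades to the model without that level, and a warning is issued), not
#' as an error.
#'
#' @param data A continuous `nested_df` with two or more groups (tests and
#'   CIs are reported per non-reference group term).
#' @param levels Random-intercept levels, outermost first: `"subject"` or
#'   `c("subject", "sample")`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param reference Reference group for the fixed-effect contrast; default
#'   first in sort order.
#' @param conf_level Confidence level for all intervals.
#' @param component_ci Compute Wald CIs for the variance components (needs
#'   a numerically differentiated Hessian; switch off in tight simulation
#'   loops where only the fixed effect is of interest).
#' @return A `uoa_lmm` object with elements `fixed` (tibble: term,
#'   estimate, std.error, df, statistic, p.value, conf.low, conf.high),
#'   `components` (tibble: level, sd, variance, conf.low, conf.high,
#'   boundary), `loglik` (REML or ML log-likelihood at the optimum),
#'   `model_data` (records with `fitted` and `residual` columns, where
#'   fitted values include the predicted random effects), `converged`,
#'   `n_iter`, and bookkeeping fields.
#' @examples
#' fit <- fit_nested_lmm(load_fixture("lymph_size"))
#' tidy(fit)
#' icc(fit)
#' @export
fit_nested_lmm <- function(data, levels = c("subject", "sample"),
                           method = c("REML", "ML"), reference = NULL,
                           conf_level = 0.95, component_ci = TRUE) {
  method <- arg_match(method)
  stopifnot(inherits(data, "nested_df"))
  if (outcome_kind(data) != "continuous") abort("continuous outcome required")
  levels <- match.arg(levels, c("subject", "sample"), several.ok = TRUE)
  if (levels[1] != "subject") abort("'levels' must start with 'subject'")
  has_sample <- "sample" %in% levels
  if (has_sample && !"sample" %in% names(data)) {
    abort("data has no 'sample' column but levels include 'sample'")
  }
  per_group <- data %>% distinct(.data$group, .data$subject) %>% count(.data$group)
  if (any(per_group$n < 2L)) abort("need at least 2 subjects per group")

  prep <- lmm_prepare(data, has_sample, reference)
  nr <- if (has_sample) 2L else 1L

  start <- lmm_start(prep, has_sample)
  theta0 <- log(pmax(start$gamma, 1e-4))

  obj <- function(theta) {
    lmm_profiled_neg2(exp(theta), prep, reml = (method == "REML"))$neg2
  }
  opt <- optim(theta0, obj, method = "L-BFGS-B",
               lower = rep(-30, nr), upper = rep(30, nr),
               control = list(factr = 1e4, maxit = 200))
  theta <- opt$par
  gamma <- exp(theta)
  boundary <- theta < -15
  core <- lmm_profiled_neg2(gamma, prep, reml = (method == "REML"))
  n <- prep$n; p <- prep$p
  sig2e <- core$rss / (if (method == "REML") n - p else n)
  sigma <- c(sqrt(gamma * sig2e), sqrt(sig2e))
  names(sigma) <- c(levels, "residual")
  loglik <- -0.5 * core$neg2

  ## Wald CIs for log(sigma) from the numerically differentiated
  ## (unprofiled-in-sigma) restricted likelihood; boundary components get NA
  ci <- matrix(NA_real_, nr + 1L, 2L)
  free <- c(!boundary, TRUE)
  fobj <- function(logsig_free) {
    logsig <- log(sigma)
    logsig[free] <- logsig_free
    -0.5 * lmm_neg2_sigma(exp(logsig), prep, reml = (method == "REML"), nr = nr)
  }
  se_log <- rep(NA_real_, nr + 1L)
  H <- if (component_ci) {
    tryCatch(pracma::hessian(fobj, log(sigma)[free]), error = function(e) NULL)
  } else NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se_log[free] <- sqrt(diag(V))
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci[, 1] <- exp(log(sigma) - zq * se_log)
  ci[, 2] <- exp(log(sigma) + zq * se_log)
  if (any(boundary)) {
    warn(sprintf(
      "variance component(s) %s estimated at the boundary (~0); inference degrades to the model without that level",
      paste(levels[boundary], collapse = ", ")))
  }

  ## fixed effects with containment df (subject-level treatment)
  beta <- core$beta
  vcov_beta <- sig2e * solve(core$A)
  se_beta <- sqrt(diag(vcov_beta))
  df_fix <- prep$n_subjects - prep$n_groups
  tcrit <- qt(1 - (1 - conf_level) / 2, df_fix)
  tstat <- beta / se_beta
  fixed <- tibble(
    term = colnames(prep$X), estimate = unname(beta),
    std.error = unname(se_beta), df = df_fix, statistic = unname(tstat),
    p.value = 2 * pt(-abs(unname(tstat)), df_fix),
    conf.low = unname(beta - tcrit * se_beta),
    conf.high = unname(beta + tcrit * se_beta)
  )

  fitted <- lmm_fitted(gamma, beta, prep)
  model_data <- prep$data
  model_data$fitted <- fitted
  model_data$residual <- prep$y - fitted

  structure(list(
    fixed = fixed,
    components = tibble(level = names(sigma), sd = unname(sigma),
                        variance = unname(sigma)^2,
                        conf.low = ci[, 1], conf.high = ci[, 2],
                        boundary = c(boundary, FALSE)),
    loglik = loglik, method = method, levels = levels,
    gamma = gamma, sigma_e = sqrt(sig2e), vcov_fixed = vcov_beta,
    model_data = model_data, converged = opt$convergence == 0L,
    n_iter = opt$counts[["function"]], n = n,
    n_subjects = prep$n_subjects, n_groups = prep$n_groups,
    reference = prep$reference, conf.level = conf_level
  ), class = "uoa_lmm")
}

## ---- internal machinery ----------------------------------------------

lmm_prepare <- function(data, has_sample, reference) {
  lev <- sort(unique(data$group))
  if (!is.null(reference)) {
    if (!reference %in% lev) abort(sprintf("unknown reference group '%s'", reference))
    lev <- c(reference, setdiff(lev, reference))
  }
  d <- as_tibble(data)
  if (has_sample) d <- arrange(d, .data$subject, .data$sample) else d <- arrange(d, .data$subject)
  g <- factor(d$group, levels = lev)
  X <- model.matrix(~g)
  colnames(X) <- c("(Intercept)", paste0("group", lev[-1]))
  y <- d$value
  subj <- factor(d$subject, levels = unique(d$subject))
  idx <- split(seq_len(nrow(d)), subj)
  reps <- lapply(idx, function(ii) {
    if (has_sample) as.integer(table(factor(d$sample[ii], levels = unique(d$sample[ii]))))
    else length(ii)
  })
  keys <- vapply(reps, paste, "", collapse = ",")
  upat <- unique(keys)
  list(
    data = d, y = y, X = X, n = nrow(d), p = ncol(X),
    idx = idx, reps = reps, pat_id = match(keys, upat),
    patterns = lapply(upat, function(k) as.integer(strsplit(k, ",")[[1]])),
    has_sample = has_sample, n_subjects = length(idx),
    n_groups = length(lev), reference = lev[1]
  )
}

lmm_make_W <- function(reps, gamma, has_sample) {
  m <- sum(reps)
  W <- diag(m) + gamma[1]
  if (has_sample && length(reps) >= 1L) {
    off <- 0L
    for (r in reps) {
      rows <- off + seq_len(r)
      W[rows, rows] <- W[rows, rows] + gamma[2]
      off <- off + r
    }
  }
  W
}

## accumulates [X y]' W^{-1} [X y] and log|W| over subject blocks
lmm_core <- function(gamma, prep) {
  chols <- lapply(prep$patterns, function(rp)
    chol(lmm_make_W(rp, gamma, prep$has_sample)))
  p <- prep$p
  C <- matrix(0, p + 1L, p + 1L)
  logdetW <- 0
  for (i in seq_along(prep$idx)) {
    R <- chols[[prep$pat_id[i]]]
    logdetW <- logdetW + 2 * sum(log(diag(R)))
    ii <- prep$idx[[i]]
    M <- backsolve(R, cbind(prep$X[ii, , drop = FALSE], prep$y[ii]),
                   transpose = TRUE)
    C <- C + crossprod(M)
  }
  A <- C[seq_len(p), seq_len(p), drop = FALSE]
  bvec <- C[seq_len(p), p + 1L]
  beta <- drop(solve(A, bvec))
  rss <- max(C[p + 1L, p + 1L] - sum(beta * bvec), 1e-300)
  list(A = A, beta = beta, rss = rss, logdetW = logdetW,
       logdetA = as.numeric(determinant(A, logarithm = TRUE)$modulus))
}

## -2 log (restricted) likelihood, profiled over beta and sigma_e
lmm_profiled_neg2 <- function(gamma, prep, reml) {
  core <- lmm_core(gamma, prep)
  n <- prep$n; p <- prep$p
  neg2 <- if (reml) {
    (n - p) * (log(2 * pi) + 1 + log(core$rss / (n - p))) +
      core$logdetW + core$logdetA
  } else {
    n * (log(2 * pi) + 1 + log(core$rss / n)) + core$logdetW
  }
  c(core, list(neg2 = neg2))
}

## -2 log (restricted) likelihood as a function of the sigmas themselves
## (beta still profiled); used for the variance-component Hessian
lmm_neg2_sigma <- function(sigma, prep, reml, nr) {
  sig2e <- sigma[nr + 1L]^2
  gamma <- sigma[seq_len(nr)]^2 / sig2e
  core <- lmm_core(gamma, prep)
  n <- prep$n; p <- prep$p
  if (reml) {
    (n - p) * log(2 * pi) + (n - p) * log(sig2e) + core$logdetW +
      core$logdetA + core$rss / sig2e
  } else {
    n * log(2 * pi) + n * log(sig2e) + core$logdetW + core$rss / sig2e
  }
}

## conditional fitted values X beta + predicted (BLUP) random effects
lmm_fitted <- function(gamma, beta, prep) {
  chols <- lapply(prep$patterns, function(rp)
    chol(lmm_make_W(rp, gamma, prep$has_sample)))
  fitted <- numeric(prep$n)
  for (i in seq_along(prep$idx)) {
    ii <- prep$idx[[i]]
    R <- chols[[prep$pat_id[i]]]
    xb <- drop(prep$X[ii, , drop = FALSE] %*% beta)
    r <- prep$y[ii] - xb
    Wr <- backsolve(R, backsolve(R, r, transpose = TRUE))
    bP <- gamma[1] * sum(Wr)
    bS <- 0
    if (prep$has_sample) {
      rp <- prep$reps[[i]]
      bS <- rep(gamma[2] * vapply(split(Wr, rep(seq_along(rp), rp)), sum, 0),
                rp)
    }
    fitted[ii] <- xb + bP + bS
  }
  fitted
}

## ANOVA method-of-moments starting values on the variance-ratio scale
lmm_start <- function(prep, has_sample) {
  d <- prep$data
  vy <- var(prep$y)
  floor_v <- max(1e-3 * vy, 1e-8)
  subj_means <- d %>% group_by(.data$group, .data$subject) %>%
    summarise(m = mean(.data$value), n = n(), .groups = "drop")
  v_between <- subj_means %>% group_by(.data$group) %>%
    summarise(v = if (n() > 1) var(.data$m) else NA_real_, .groups = "drop")
  v_between <- mean(v_between$v, na.rm = TRUE)
  if (!is.finite(v_between)) v_between <- vy
  m_bar <- mean(subj_means$n)
  if (has_sample) {
    cell <- d %>% group_by(.data$subject, .data$sample) %>%
      summarise(m = mean(.data$value), v = if (n() > 1) var(.data$value) else NA_real_,
                n = n(), .groups = "drop")
    v_e <- mean(cell$v, na.rm = TRUE)
    if (!is.finite(v_e)) v_e <- 0.1 * vy
    r_bar <- mean(cell$n)
    v_sw <- cell %>% group_by(.data$subject) %>%
      summarise(v = if (n() > 1) var(.data$m) else NA_real_, .groups = "drop")
    v_sw <- mean(v_sw$v, na.rm = TRUE)
    if (!is.finite(v_sw)) v_sw <- 0.2 * vy
    s_bar <- m_bar / r_bar
    sig2S <- max(v_sw - v_e / r_bar, floor_v)
    sig2P <- max(v_between - v_sw / s_bar, floor_v)
    sig2e <- max(v_e, floor_v)
    list(gamma = c(sig2P, sig2S) / sig2e)
  } else {
    v_within <- d %>% group_by(.data$subject) %>%
      summarise(v = if (n() > 1) var(.data$value) else NA_real_, .groups = "drop")
    v_e <- mean(v_within$v, na.rm = TRUE)
    if (!is.finite(v_e)) v_e <- 0.5 * vy
    sig2P <- max(v_between - v_e / m_bar, floor_v)
    sig2e <- max(v_e, floor_v)
    list(gamma = sig2P / sig2e)
  }
}

## ---- methods ----------------------------------------------------------

#' @export
print.uoa_lmm <- function(x, ...) {
  cat(sprintf("Nested linear mixed model (%s), %d records / %d subjects\n",
              x$method, x$n, x$n_subjects))
  cat(sprintf("  random intercepts: %s; log-likelihood %.4f\n",
              paste(x$levels, collapse = " / "), x$loglik))
  cat("Variance components (SD scale):\n")
  print(as.data.frame(x$components), digits = 4)
  cat(sprintf("Fixed effects (stratum df = %d):\n", x$fixed$df[1]))
  print(as.data.frame(x$fixed), digits = 4)
  invisible(x)
}

#' Tidiers for nested LMM fits
#'
#' `tidy()` returns fixed-effect terms and/or variance components in broom
#' style; `glance()` returns a one-row model summary.
#'
#' @param x A `uoa_lmm`.
#' @param effects `"fixed"`, `"ran_pars"`, or both.
#' @param ... Unused.
#' @export
tidy.uoa_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- mutate(x$fixed, effect = "fixed", .before = 1)
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble(
      effect = "ran_pars", term = paste0("sd__", x$components$level),
      estimate = x$components$sd, std.error = NA_real_, df = NA_real_,
      statistic = NA_real_, p.value = NA_real_,
      conf.low = x$components$conf.low, conf.high = x$components$conf.high
    )
  }
  bind_rows(out)
}

#' @rdname tidy.uoa_lmm
#' @export
glance.uoa_lmm <- function(x, ...) {
  tibble(logLik = x$loglik, method = x$method,
         sigma = x$sigma_e, nobs = x$n, n_subjects = x$n_subjects,
         converged = x$converged, icc_subject = icc(x))
}

#' Intraclass correlation coefficient
#'
#' The proportion of total outcome variance attributable to a nesting
#' level: for subjects, `ICC_P = sigma_P^2 / (sigma_P^2 + sigma_S^2 +
#' sigma_e^2)`; equivalently the correlation between two randomly chosen
#' observations on the same subject. An ICC of 0 is the independence
#' assumption of the naive analysis.
#'
#' @param components A `uoa_lmm` fit, or a named numeric vector of standard
#'   deviations (e.g. `c(subject = 0.4, sample = 0.2, residual = 0.1)`).
#' @param level Level whose ICC is required (currently `"subject"`).
#' @return A number in \[0, 1\].
#' @examples
#' icc(c(subject = 0.4, sample = 0.2, residual = 0.1))
#' @export
icc <- function(components, level = "subject") {
  sds <- if (inherits(components, "uoa_lmm")) {
    setNames(components$components$sd, components$components$level)
  } else {
    components
  }
  if (any(sds < 0)) abort("standard deviations must be non-negative")
  if (all(sds == 0)) abort("all variance components are zero: ICC undefined")
  if (!level %in% names(sds)) abort(sprintf("unknown level '%s'", level))
  unname(sds[level]^2 / sum(sds^2))
}

#' Likelihood-ratio test between random-effects structures
#'
#' Compares two fits of the same fixed-effect model (and same estimation
#' method) whose random structures are nested, e.g. subject + sample versus
#' subject only: `LRT = 2 * (loglik_full - loglik_reduced)`, floored at
#' zero, referred to a chi-squared distribution with df equal to the number
#' of extra variance parameters. Because the null value of a variance lies
#' on the parameter boundary, the naive chi-squared p-value is
#' conservative; for df = 1 the 50:50 mixture of a point mass at zero and
#' chi-squared(1) is also reported.
#'
#' @param full,reduced `uoa_lmm` fits with identical fixed effects; the
#'   reduced random structure must be nested in the full one.
#' @return A `uoa_lrt` list: `statistic`, `df`, `p.value` (naive
#'   chi-squared), `p.boundary` (mixture, df = 1 only).
#' @examples
#' d <- load_fixture("lymph_size")
#' lrt_random_structure(fit_nested_lmm(d), fit_nested_lmm(d, levels = "subject"))
#' @export
lrt_random_structure <- function(full, reduced) {
  stopifnot(inherits(full, "uoa_lmm"), inherits(reduced, "uoa_lmm"))
  if (full$method != reduced$method) abort("fits use different estimation methods")
  if (!identical(full$fixed$term, reduced$fixed$term)) {
    abort("fixed effects differ between fits; LRT on random structures refused")
  }
  if (!all(reduced$levels %in% full$levels)) {
    abort("reduced random structure is not nested in the full one")
  }
  df <- length(full$levels) - length(reduced$levels)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) {
    if (stat > 0) 0 else 1
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  p_boundary <- if (df == 1L) {
    if (stat == 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  } else NA_real_
  structure(list(statistic = stat, df = df, p.value = p,
                 p.boundary = p_boundary), class = "uoa_lrt")
}

#' @export
print.uoa_lrt <- function(x, ...) {
  cat(sprintf("LRT = %.3f on %d df, p = %.4g (boundary-mixture p = %.4g)\n",
              x$statistic, x$df, x$p.value, x$p.boundary))
  invisible(x)
}

#' Residual diagnostics for a nested LMM fit
#'
#' Conditional residuals (observed minus fitted, where fitted values
#' include the predicted random effects) summarised per subject as boxplot
#' statistics, plus ordered residuals paired with theoretical Normal
#' quantiles scaled by the fitted residual SD, for a Q-Q assessment of the
#' Normality assumption.
#'
#' @param fit A converged `uoa_lmm`.
#' @return A `uoa_lmm_diag` list: `residuals` (per-record tibble),
#'   `by_subject` (median/quartiles/whiskers per subject), `qq`
#'   (`theoretical`, `observed`).
#' @examples
#' lmm_diagnostics(fit_nested_lmm(load_fixture("lymph_size")))
#' @export
lmm_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "uoa_lmm"))
  if (!fit$converged) abort("fit did not converge")
  md <- fit$model_data
  res <- tibble(group = md$group, subject = md$subject,
                fitted = md$fitted, residual = md$residual)
  if ("sample" %in% names(md)) res$sample <- md$sample
  by_subject <- res %>%
    group_by(.data$group, .data$subject) %>%
    summarise(
      n = n(), median = median(.data$residual),
      q1 = quantile(.data$residual, 0.25), q3 = quantile(.data$residual, 0.75),
      .groups = "drop") %>%
    mutate(
      whisker_low = .data$q1 - 1.5 * (.data$q3 - .data$q1),
      whisker_high = .data$q3 + 1.5 * (.data$q3 - .data$q1)
    )
  r <- sort(res$residual)
  qq <- tibble(theoretical = qnorm(stats::ppoints(length(r))) * fit$sigma_e,
               observed = r)
  structure(list(residuals = res, by_subject = by_subject, qq = qq),
            class = "uoa_lmm_diag")
}

#' @rdname lmm_diagnostics
#' @param object A `uoa_lmm_diag` (or, for the `uoa_lmm` method, a fit).
#' @param type `"residuals"` for per-subject boxplots, `"qq"` for the
#'   Normal quantile plot.
#' @param ... Unused.
#' @export
autoplot.uoa_lmm_diag <- function(object, type = c("residuals", "qq"), ...) {
  type <- match.arg(type)
  if (type == "residuals") {
    ggplot2::ggplot(object$residuals,
                    ggplot2::aes(x = .data$subject, y = .data$residual)) +
      ggplot2::geom_boxplot(ggplot2::aes(fill = .data$group), alpha = 0.5) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "subject", y = "residual (observed - fitted)")
  } else {
    ggplot2::ggplot(object$qq,
                    ggplot2::aes(x = .data$observed, y = .data$theoretical)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(shape = 1) +
      ggplot2::labs(x = "model residuals", y = "theoretical Normal residuals")
  }
}

#' @rdname lmm_diagnostics
#' @export
autoplot.uoa_lmm <- function(object, type = c("residuals", "qq"), ...) {
  autoplot(lmm_diagnostics(object), type = type, ...)
}
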
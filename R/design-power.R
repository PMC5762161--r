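#' Variance inflation factor (design effect) for clustered observations
#'
#' `VIF = 1 + (m - 1) * ICC` for clusters of `m` observations with
#' intraclass correlation `ICC`: the factor by which a naive sample-size
#' calculation must be inflated when observations cluster. Vectorised over
#' both arguments.
#'
#' @param m Observations per cluster (integer >= 1).
#' @param icc Intraclass correlation in \[0, 1).
#' @return `1 + (m - 1) * icc`.
#' @examples
#' vif(20, 0.5)
#' @export
vif <- function(m, icc) {
  if (any(m < 1)) abort("'m' must be >= 1")
  if (any(icc < 0 | icc >= 1)) abort("'icc' must be in [0, 1)")
  1 + (m - 1) * icc
}

#' Grid of variance inflation factors
#'
#' @param m Vector of cluster sizes.
#' @param icc Vector of intraclass correlations.
#' @return A tibble with columns `m`, `icc`, `vif`, one row per
#'   combination.
#' @examples
#' vif_table()
#' @export
vif_table <- function(m = c(2, 5, 10, 20), icc = c(0.01, 0.05, 0.1, 0.5)) {
  grid <- tidyr::expand_grid(m = m, icc = icc)
  mutate(grid, vif = vif(.data$m, .data$icc))
}

#' Two-group sample size for a Normal outcome
#'
#' `n = 2 sigma^2 (z_{alpha/2} + z_beta)^2 / d^2` subjects per group to
#' detect a difference `d` in means with two-sided significance level
#' `alpha` and the given power, for outcome standard deviation `sigma`.
#' At `alpha = 0.05` and 90% power the multiplier
#' `(z_{alpha/2} + z_beta)^2 = (1.96 + 1.28)^2` is about 10.5.
#'
#' @param sigma Outcome standard deviation (outcome units).
#' @param d Difference to detect (outcome units, > 0).
#' @param alpha Two-sided significance level.
#' @param power Target power (probability of detecting `d`).
#' @return A tibble with `n_raw` (formula value), `n` (ceiling),
#'   `multiplier`.
#' @examples
#' sample_size_two_group(sigma = 1, d = 0.5)
#' @export
sample_size_two_group <- function(sigma, d, alpha = 0.05, power = 0.9) {
  if (alpha <= 0 || alpha >= 1) abort("'alpha' must be in (0, 1)")
  if (power <= 0 || power >= 1) abort("'power' must be in (0, 1)")
  if (d <= 0) abort("'d' must be > 0")
  if (sigma <= 0) abort("'sigma' must be > 0")
  mult <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  n_raw <- 2 * sigma^2 * mult / d^2
  tibble(n_raw = n_raw, n = ceiling(n_raw), multiplier = mult)
}

#' Inflate a sample size for clustering
#'
#' Multiplies a per-group sample size by the design effect
#' [vif()]: `n * (1 + (m - 1) * icc)`.
#'
#' @param n Uninflated sample size (subjects per group).
#' @param m Observations per cluster.
#' @param icc Intraclass correlation.
#' @return The inflated (possibly non-integer) sample size.
#' @examples
#' inflate_for_clustering(21, m = 5, icc = 0.1)
#' @export
inflate_for_clustering <- function(n, m, icc) n * vif(m, icc)

#' Error degrees of freedom per stratum (resource-equation check)
#'
#' For a balanced nested design with `n_groups` treatment groups,
#' `subjects_per_group` subjects, `samples_per_subject` samples and
#' `replicates_per_sample` replicates, standard nested-ANOVA bookkeeping
#' gives the error df at each stratum: subjects
#' (`G*n - G`, the stratum against which a subject-level treatment is
#' tested), samples within subjects (`G*n*s - G*n`), replicates within
#' samples (`G*n*s*r - G*n*s`). The resource-equation rule of thumb calls
#' a stratum adequate when its error df is at least 15.
#'
#' @param n_groups,subjects_per_group,samples_per_subject,replicates_per_sample
#'   Balanced layout counts (all >= 1).
#' @return A tibble with columns `stratum`, `error_df`, `adequate`.
#' @examples
#' resource_equation_check(2, 6, 2, 3)
#' @export
resource_equation_check <- function(n_groups, subjects_per_group,
                                    samples_per_subject = 1L,
                                    replicates_per_sample = 1L) {
  counts <- c(n_groups, subjects_per_group, samples_per_subject,
              replicates_per_sample)
  if (any(counts < 1)) abort("all layout counts must be >= 1")
  n_subj <- n_groups * subjects_per_group
  n_samp <- n_subj * samples_per_subject
  n_obs <- n_samp * replicates_per_sample
  out <- tibble(
    stratum = c("subject", "sample", "replicate"),
    error_df = as.integer(c(n_subj - n_groups, n_samp - n_subj, n_obs - n_samp))
  )
  mutate(out, adequate = .data$error_df >= 15L)
}

#' Layout specification for a balanced nested design
#'
#' @param n_groups Number of treatment groups.
#' @param subjects_per_group Subjects (experimental units) per group.
#' @param samples_per_subject Samples per subject.
#' @param replicates_per_sample Replicate measurements per sample.
#' @return A `uoa_layout` list.
#' @export
design_layout <- function(n_groups = 2L, subjects_per_group = 6L,
                          samples_per_subject = 2L,
                          replicates_per_sample = 3L) {
  counts <- c(n_groups = n_groups, subjects_per_group = subjects_per_group,
              samples_per_subject = samples_per_subject,
              replicates_per_sample = replicates_per_sample)
  if (any(counts < 1)) abort("all layout counts must be >= 1")
  structure(as.list(counts), class = "uoa_layout")
}

#' Simulate a balanced nested Gaussian dataset
#'
#' Draws `y = mu + effect * [first group] + b_subject + b_sample + e` with
#' independent Normal random effects at each level:
#' `b_subject ~ N(0, sigma_P^2)`, `b_sample ~ N(0, sigma_S^2)`,
#' `e ~ N(0, sigma_e^2)`. The treatment effect is added to the first
#' group's mean. Deterministic for a given seed.
#'
#' @param layout A [design_layout()].
#' @param effect Treatment effect (added to group `G1`).
#' @param components Named SDs `c(subject =, sample =, residual =)`.
#' @param seed Integer seed.
#' @param mu Grand mean (nuisance; default 0).
#' @return A continuous `nested_df`.
#' @examples
#' simulate_nested_dataset(design_layout(), 0,
#'   c(subject = 0.4, sample = 0.2, residual = 0.1), seed = 1)
#' @export
simulate_nested_dataset <- function(layout, effect, components, seed, mu = 0) {
  stopifnot(inherits(layout, "uoa_layout"))
  need <- c("subject", "sample", "residual")
  if (!all(need %in% names(components))) {
    abort("components must be named c(subject=, sample=, residual=)")
  }
  if (any(components[need] < 0)) abort("components must be non-negative")
  G <- layout$n_groups; n <- layout$subjects_per_group
  s <- layout$samples_per_subject; r <- layout$replicates_per_sample
  d <- tidyr::expand_grid(
    group_i = seq_len(G), subj_i = seq_len(n), samp_i = seq_len(s),
    rep_i = seq_len(r))
  n_subj <- G * n; n_samp <- n_subj * s
  subj_id <- (d$group_i - 1L) * n + d$subj_i
  samp_id <- (subj_id - 1L) * s + d$samp_i
  withr::with_seed(seed, {
    bP <- rnorm(n_subj, 0, components[["subject"]])
    bS <- rnorm(n_samp, 0, components[["sample"]])
    e <- rnorm(nrow(d), 0, components[["residual"]])
  })
  y <- mu + effect * (d$group_i == 1L) + bP[subj_id] + bS[samp_id] + e
  as_nested_data(tibble(
    group = paste0("G", d$group_i),
    subject = sprintf("S%03d", subj_id),
    sample = as.character(d$samp_i),
    replicate = as.character(d$rep_i),
    value = y
  ), "continuous")
}

#' Monte-Carlo study of analysis operating characteristics
#'
#' Repeatedly simulates nested Gaussian data from a given layout and
#' variance components, analyses each replicate with the requested methods
#' (naive pooled t-test, subject-based t-test, and/or the nested mixed
#' model with stratum df), and aggregates rejection rate at level `alpha`,
#' mean estimate of the group difference, CI width and coverage. With
#' `effect = 0` the rejection rate is the type-I error: the naive analysis
#' inflates it by roughly the design effect (rejecting at about
#' `2 * pnorm(-qnorm(1 - alpha/2) / sqrt(vif(m, icc)))` in the many-subject
#' limit), while the subject-based and mixed analyses hold the nominal
#' level.
#'
#' The mixed analysis fits random intercepts for subject and sample when
#' the layout has genuine replication at both levels, otherwise subject
#' only. Replicate `r` uses a deterministic seed substream derived from
#' `(seed, r)`. Replicates whose mixed fit fails are dropped and counted;
#' more than 1% failures is an error.
#'
#' @param layout A [design_layout()].
#' @param effect True treatment effect (difference in group means).
#' @param components Named SDs `c(subject =, sample =, residual =)`.
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param alpha Two-sided significance level for rejection.
#' @param methods Subset of `c("naive", "subject_based", "mixed")`.
#' @param seed Integer seed.
#' @return A `uoa_sim` object whose `results` tibble has one row per
#'   method: `rejection_rate`, `mc_se`, `mean_estimate`, `mean_ci_width`,
#'   `coverage`, `n_ok`.
#' @examples
#' run_simulation_study(design_layout(2, 6, 2, 3), 0,
#'   c(subject = 0.4, sample = 0.2, residual = 0.1),
#'   n_reps = 100, methods = "naive", seed = 1)
#' @export
run_simulation_study <- function(layout, effect, components, n_reps = 1000L,
                                 alpha = 0.05,
                                 methods = c("naive", "subject_based", "mixed"),
                                 seed = 1L) {
  stopifnot(inherits(layout, "uoa_layout"))
  if (n_reps < 100L) abort("'n_reps' must be >= 100")
  methods <- match.arg(methods, several.ok = TRUE)
  conf_level <- 1 - alpha
  mixed_levels <- if (layout$samples_per_subject > 1L &&
                      layout$replicates_per_sample > 1L) {
    c("subject", "sample")
  } else "subject"
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))

  one_rep <- function(r) {
    d <- simulate_nested_dataset(layout, effect, components, seed = rep_seeds[r])
    rows <- list()
    analyse <- function(est, lo, hi, p) {
      c(estimate = est, conf.low = lo, conf.high = hi,
        reject = as.numeric(p < alpha), covered = as.numeric(lo <= effect & effect <= hi))
    }
    if ("naive" %in% methods) {
      tt <- pooled_t_test(d, conf_level = conf_level)
      rows$naive <- analyse(tt$difference, tt$conf.int[1], tt$conf.int[2], tt$p.value)
    }
    if ("subject_based" %in% methods) {
      tt <- suppressWarnings(subject_based_t_test(d, conf_level = conf_level))
      rows$subject_based <- analyse(tt$difference, tt$conf.int[1], tt$conf.int[2], tt$p.value)
    }
    if ("mixed" %in% methods) {
      fit <- tryCatch(
        suppressWarnings(fit_nested_lmm(d, levels = mixed_levels,
                                        conf_level = conf_level,
                                        reference = "G2",
                                        component_ci = FALSE)),
        error = function(e) NULL)
      rows$mixed <- if (is.null(fit)) {
        c(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
          reject = NA_real_, covered = NA_real_)
      } else {
        ## term is G1 - G2, matching the t-test difference (G1 carries the effect)
        fx <- fit$fixed[2, ]
        analyse(fx$estimate, fx$conf.low, fx$conf.high, fx$p.value)
      }
    }
    rows
  }

  reps <- lapply(seq_len(n_reps), one_rep)
  results <- purrr::map_dfr(methods, function(mth) {
    m <- do.call(rbind, lapply(reps, `[[`, mth))
    ok <- stats::complete.cases(m)
    n_fail <- sum(!ok)
    if (n_fail > 0.01 * n_reps) {
      abort(sprintf("method '%s': %d/%d replicate fits failed", mth, n_fail, n_reps))
    }
    m <- m[ok, , drop = FALSE]
    rate <- mean(m[, "reject"])
    tibble(
      method = mth, rejection_rate = rate,
      mc_se = sqrt(rate * (1 - rate) / nrow(m)),
      mean_estimate = mean(m[, "estimate"]),
      mean_ci_width = mean(m[, "conf.high"] - m[, "conf.low"]),
      coverage = mean(m[, "covered"]), n_ok = nrow(m), n_fail = n_fail
    )
  })
  structure(list(results = results, layout = layout, effect = effect,
                 components = components, n_reps = n_reps, alpha = alpha,
                 seed = seed), class = "uoa_sim")
}

#' @export
print.uoa_sim <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo study: %d reps, effect = %g, alpha = %g, seed = %d\n",
    x$n_reps, x$effect, x$alpha, x$seed))
  cat(sprintf("  layout: %d groups x %d subjects x %d samples x %d replicates; sigma = (%s)\n",
              x$layout$n_groups, x$layout$subjects_per_group,
              x$layout$samples_per_subject, x$layout$replicates_per_sample,
              paste(x$components, collapse = ", ")))
  print(as.data.frame(x$results), digits = 4)
  invisible(x)
}

#' @rdname run_simulation_study
#' @param x A `uoa_sim`.
#' @param ... Unused.
#' @export
tidy.uoa_sim <- function(x, ...) x$results

#' @rdname run_simulation_study
#' @param object A `uoa_sim`.
#' @export
autoplot.uoa_sim <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$rejection_rate)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$rejection_rate - 2 * .data$mc_se,
      ymax = .data$rejection_rate + 2 * .data$mc_se), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::labs(y = sprintf("rejection rate at alpha = %g", object$alpha))
}

#' Run the Monte-Carlo study grid from a YAML configuration
#'
#' The configuration holds a list of named scenarios, each with a `layout`
#' (n_groups, subjects_per_group, samples_per_subject,
#' replicates_per_sample), `components` (subject, sample, residual SDs),
#' `effect`, and optional `n_reps`, `alpha`, `methods`. The packaged
#' default grid lives at
#' `system.file("extdata", "sim_study.yaml", package = "uoa")`.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @param seed Integer seed; scenario `i` uses substream `seed + i - 1`.
#' @return A tibble of per-scenario, per-method operating characteristics.
#' @export
run_simulation_config <- function(config, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  scenarios <- config$scenarios %||% abort("config needs a 'scenarios' list")
  purrr::imap_dfr(scenarios, function(sc, nm) {
    lay <- do.call(design_layout, sc$layout)
    comp <- unlist(sc$components)
    sim <- run_simulation_study(
      lay, effect = sc$effect %||% 0, components = comp,
      n_reps = sc$n_reps %||% config$n_reps %||% 1000L,
      alpha = sc$alpha %||% config$alpha %||% 0.05,
      methods = sc$methods %||% c("naive", "subject_based", "mixed"),
      seed = seed + match(nm, names(scenarios)) - 1L)
    mutate(tidy(sim), scenario = nm, .before = 1)
  })
}
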
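#' Audit the unit of analysis of a planned analysis
#'
#' Emits a warning record when the analysis level sits below the level at
#' which treatment was assigned — the classic unit-of-analysis mismatch in
#' which within-unit variability is used to judge a between-unit treatment,
#' inflating the type-I error. Also flags unbalanced designs, where the
#' subject-summary analysis loses validity.
#'
#' @param data A `nested_df`.
#' @param treatment_level Stratum at which treatment is assigned
#'   (`"subject"`, `"sample"`, or `"replicate"`).
#' @param analysis_level Stratum whose observations enter the analysis.
#' @return A tibble with columns `code` and `message` (zero rows when the
#'   analysis is sound), with attribute `balanced`.
#' @examples
#' audit_units(load_fixture("lymph_size"), "subject", "replicate")
#' @export
audit_units <- function(data, treatment_level = "subject", analysis_level) {
  stopifnot(inherits(data, "nested_df"))
  strata <- c("subject", "sample", "replicate")
  present <- c("subject", intersect(c("sample", "replicate"), names(data)))
  for (lv in c(treatment_level, analysis_level)) {
    if (!lv %in% present) abort(sprintf("unknown stratum '%s' for this dataset", lv))
  }
  warnings <- tibble(code = character(), message = character())
  if (match(analysis_level, strata) > match(treatment_level, strata)) {
    warnings <- bind_rows(warnings, tibble(
      code = "uoa_mismatch",
      message = sprintf(
        "treatment assigned at the %s level but analysis requested at the %s level: observation-level tests pseudoreplicate and inflate the false-positive rate",
        treatment_level, analysis_level)))
  }
  summ <- dataset_summary(data)
  if (!summ$balanced) {
    warnings <- bind_rows(warnings, tibble(
      code = "unbalanced",
      message = "design is unbalanced: subject summaries carry unequal precision; prefer the mixed model"))
  }
  structure(warnings, balanced = summ$balanced)
}

#' Side-by-side analysis report
#'
#' Runs the requested analyses on one dataset and collects their tidy
#' results, the dataset summary, and any unit-of-analysis warnings into a
#' single deterministic report. For a continuous outcome the available
#' analyses are `"naive"`, `"subject_based"` and `"mixed"`; for a binomial
#' outcome, `"glm"` and `"glmm"`.
#'
#' @param data A `nested_df`.
#' @param analyses Character vector of analyses to run (default: all that
#'   apply to the outcome kind). May be empty for a summary-only report.
#' @param conf_level Confidence level passed to every analysis.
#' @param reference Optional reference group passed to every analysis.
#' @return A `uoa_report` list: `summary`, `results` (named list of tidy
#'   tibbles), `warnings`.
#' @examples
#' uoa_report(load_fixture("lymph_size"))
#' @export
uoa_report <- function(data, analyses = NULL, conf_level = 0.95,
                       reference = NULL) {
  stopifnot(inherits(data, "nested_df"))
  kind <- outcome_kind(data)
  all_an <- if (kind == "continuous") c("naive", "subject_based", "mixed") else c("glm", "glmm")
  if (is.null(analyses)) analyses <- all_an
  bad <- setdiff(analyses, all_an)
  if (length(bad)) {
    abort(sprintf("analysis(es) %s unavailable for a %s outcome",
                  paste(bad, collapse = ", "), kind))
  }
  summ <- dataset_summary(data)
  results <- list()
  for (an in analyses) {
    results[[an]] <- switch(
      an,
      naive = tidy(pooled_t_test(data, conf_level, reference)),
      subject_based = tidy(suppressWarnings(
        subject_based_t_test(data, conf_level, reference))),
      mixed = tidy(suppressWarnings(
        fit_nested_lmm(data, conf_level = conf_level, reference = reference))),
      glm = tidy(fit_logistic_glm(data, conf_level, reference)),
      glmm = tidy(fit_logistic_glmm(data, conf_level = conf_level,
                                    reference = reference))
    )
  }
  warn_level <- if (kind == "continuous" && "sample" %in% names(data)) "replicate" else "sample"
  warn_level <- intersect(c(warn_level, "sample", "subject"), names(data))[1]
  warnings <- audit_units(data, "subject",
                          if ("naive" %in% analyses || "glm" %in% analyses)
                            warn_level else "subject")
  structure(list(
    summary = summ[c("n_records", "n_subjects", "n_groups", "outcome_kind",
                     "balanced")],
    results = results,
    warnings = as_tibble(warnings)
  ), class = "uoa_report")
}

#' @export
print.uoa_report <- function(x, ...) {
  cat(render_report_markdown(x))
  invisible(x)
}

#' Render a report as JSON or markdown
#'
#' JSON output round-trips: parsing the JSON recovers the report values.
#' Floating-point values are serialised at full precision.
#'
#' @param report A `uoa_report`.
#' @param digits Significant digits for markdown rendering.
#' @return A character scalar.
#' @export
render_report_json <- function(report) {
  stopifnot(inherits(report, "uoa_report"))
  jsonlite::toJSON(unclass(report), dataframe = "rows", auto_unbox = TRUE,
                   digits = NA, pretty = TRUE)
}

#' @rdname render_report_json
#' @export
render_report_markdown <- function(report, digits = 6) {
  stopifnot(inherits(report, "uoa_report"))
  s <- report$summary
  lines <- c(
    "# Unit-of-analysis report", "",
    sprintf("- records: %d; subjects: %d; groups: %d; outcome: %s; balanced: %s",
            s$n_records, s$n_subjects, s$n_groups, s$outcome_kind, s$balanced), "")
  if (nrow(report$warnings)) {
    lines <- c(lines, "## Warnings", "",
               sprintf("- [%s] %s", report$warnings$code, report$warnings$message), "")
  }
  for (nm in names(report$results)) {
    df <- as.data.frame(report$results[[nm]])
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits)
    lines <- c(lines, sprintf("## %s", nm), "",
               utils::capture.output(print(df, row.names = FALSE)), "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
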
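#' Nested long-format datasets
#'
#' A nested dataset is a long-format tibble in which each row is one
#' observation from a hierarchical laboratory design: a treatment `group`
#' applied at the `subject` level (the experimental unit), optional `sample`
#' and `replicate` labels nesting below the subject, and either a continuous
#' outcome column `value` or a binomial pair `events`/`trials` (events out of
#' trials per row). `as_nested_data()` validates a data frame and stamps it
#' with the outcome kind; all analysis functions in the package accept the
#' result.
#'
#' Validity requirements:
#' * every subject belongs to exactly one group (treatment is assigned to
#'   subjects);
#' * `(subject, sample, replicate)` label combinations are unique;
#' * binomial rows satisfy `0 <= events <= trials`, `trials >= 1`;
#' * a dataset is either continuous or binomial, never both.
#'
#' Sample labels are nested: sample "1" of subject 1 and sample "1" of
#' subject 2 are different physical samples, and all internal computations
#' key on the (subject, sample) pair.
#'
#' @param data A data frame with columns `group`, `subject`, and either
#'   `value` (continuous) or `events` and `trials` (binomial); `sample` and
#'   `replicate` are optional.
#' @param outcome_kind `"continuous"` or `"binomial"`; inferred from the
#'   columns when `NULL`.
#' @return A tibble of class `nested_df` with an `outcome_kind` attribute.
#' @examples
#' d <- load_fixture("lymph_size")
#' outcome_kind(d)
#' @export
as_nested_data <- function(data, outcome_kind = NULL) {
  data <- as_tibble(data)
  if (is.null(outcome_kind)) {
    outcome_kind <- if ("value" %in% names(data)) "continuous" else "binomial"
  }
  outcome_kind <- arg_match0(outcome_kind, c("continuous", "binomial"))

  for (col in c("group", "subject")) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' is required in a nested dataset", col))
    }
    data[[col]] <- as.character(data[[col]])
  }
  for (col in intersect(c("sample", "replicate"), names(data))) {
    data[[col]] <- as.character(data[[col]])
  }

  if (nrow(data) == 0L) abort("nested dataset has no records")

  if (outcome_kind == "continuous") {
    if (!"value" %in% names(data)) abort("continuous data need a 'value' column")
    if ("events" %in% names(data) || "trials" %in% names(data)) {
      abort("continuous and binomial outcomes are mutually exclusive")
    }
    data$value <- as.numeric(data$value)
    if (anyNA(data$value)) abort("missing values in 'value'; drop those records")
  } else {
    if (!all(c("events", "trials") %in% names(data))) {
      abort("binomial data need 'events' and 'trials' columns")
    }
    if ("value" %in% names(data)) {
      abort("continuous and binomial outcomes are mutually exclusive")
    }
    data$events <- as.integer(data$events)
    data$trials <- as.integer(data$trials)
    if (anyNA(data$events) || anyNA(data$trials)) {
      abort("missing values in 'events'/'trials'; drop those records")
    }
    if (any(data$trials < 1L)) abort("'trials' must be >= 1")
    if (any(data$events < 0L | data$events > data$trials)) {
      abort("validation error: 'events' must satisfy 0 <= events <= trials")
    }
  }

  ng <- data %>% distinct(.data$subject, .data$group) %>% count(.data$subject)
  if (any(ng$n > 1L)) {
    abort(sprintf(
      "validation error: subject(s) %s appear in more than one group",
      paste(ng$subject[ng$n > 1L], collapse = ", ")
    ))
  }

  keys <- data[intersect(c("subject", "sample", "replicate"), names(data))]
  if (anyDuplicated(keys)) {
    abort("validation error: duplicate (subject, sample, replicate) records")
  }

  data <- arrange(data, .data$group, .data$subject,
                  across(all_of(intersect(c("sample", "replicate"), names(data)))))
  structure(data, class = c("nested_df", class(data)),
            outcome_kind = outcome_kind)
}

#' @rdname as_nested_data
#' @param x A `nested_df`.
#' @export
outcome_kind <- function(x) attr(x, "outcome_kind") %||% "continuous"

#' @export
print.nested_df <- function(x, ...) {
  cat(sprintf("<nested dataset: %s outcome, %d records, %d subjects, %d groups>\n",
              outcome_kind(x), nrow(x), n_distinct(x$subject),
              n_distinct(x$group)))
  NextMethod()
}

#' Read a long-format nested dataset from CSV/TSV
#'
#' Reads delimited long-format data, renames columns according to `col_map`,
#' drops rows whose outcome cell is missing or a `"-"` placeholder (these are
#' absent records, as in printed tables of unbalanced designs, not zeros),
#' and validates the result with [as_nested_data()].
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param outcome_kind `"continuous"` or `"binomial"`.
#' @param col_map Optional named character vector mapping standard names to
#'   file column names, e.g. `c(value = "size_mm")`. Standard names:
#'   `group`, `subject`, `sample`, `replicate`, `value`, `events`, `trials`.
#' @param delim Field delimiter; `","` (default) or `"\t"` for TSV.
#' @return A validated `nested_df`.
#' @export
read_long_csv <- function(path, outcome_kind = c("continuous", "binomial"),
                          col_map = NULL, delim = ",") {
  outcome_kind <- arg_match(outcome_kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (nrow(raw) == 0L) abort("validation error: file contains no records")
  if (!is.null(col_map)) {
    bad <- setdiff(unname(col_map), names(raw))
    if (length(bad)) abort(sprintf("mapped column(s) absent: %s", paste(bad, collapse = ", ")))
    names(raw)[match(unname(col_map), names(raw))] <- names(col_map)
  }
  outcome_cols <- if (outcome_kind == "continuous") "value" else c("events", "trials")
  missing_cols <- setdiff(c("group", "subject", outcome_cols), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("required column(s) absent: %s", paste(missing_cols, collapse = ", ")))
  }
  is_missing <- rep(FALSE, nrow(raw))
  for (col in outcome_cols) {
    cell <- trimws(raw[[col]])
    is_missing <- is_missing | cell == "" | cell == "-" | is.na(cell)
  }
  raw <- raw[!is_missing, , drop = FALSE]
  if (nrow(raw) == 0L) abort("validation error: all records have missing outcomes")
  as_nested_data(raw, outcome_kind)
}

#' Write a nested dataset to CSV/TSV
#'
#' Inverse of [read_long_csv()]: writing then reading back reproduces the
#' records (up to row order, which is normalised on validation).
#'
#' @param data A `nested_df`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path, delim = ",") {
  stopifnot(inherits(data, "nested_df"))
  readr::write_delim(as_tibble(data), path, delim = delim, na = "")
  invisible(path)
}

#' Packaged example datasets
#'
#' Two fully printed datasets from a colorectal-cancer radiotherapy study
#' ship with the package (see `inst/extdata/MANIFEST.md` for provenance):
#'
#' * `"lymph_size"`: lymph-node sizes (mm) for 12 subjects (6 no
#'   radiotherapy, 6 short-course radiotherapy), 2 tissue samples per
#'   subject, 3 slices per sample; 72 continuous observations.
#' * `"lymph_count"`: number of 5 randomly selected lymph nodes with
#'   maximum diameter at least 2 mm, for up to 5 samples per subject;
#'   50 binomial records (events out of 5), unbalanced.
#'
#' @param name `"lymph_size"` or `"lymph_count"`.
#' @return A validated `nested_df`.
#' @examples
#' load_fixture("lymph_size")
#' @export
load_fixture <- function(name = c("lymph_size", "lymph_count")) {
  name <- arg_match(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "uoa",
                      mustWork = TRUE)
  kind <- if (name == "lymph_size") "continuous" else "binomial"
  read_long_csv(path, outcome_kind = kind)
}

#' Randomly unbalance a dataset
#'
#' Removes a fraction of the records uniformly at random, subject to every
#' subject keeping at least one observation, emulating sample loss or
#' contamination in an otherwise balanced design. Deterministic for a given
#' seed.
#'
#' @param data A `nested_df`.
#' @param fraction Fraction of records to remove, in (0, 1).
#' @param seed Integer seed.
#' @return A `nested_df` with `round(nrow(data) * (1 - fraction))` records.
#' @export
remove_fraction <- function(data, fraction, seed) {
  stopifnot(inherits(data, "nested_df"))
  if (fraction <= 0) return(data)
  if (fraction >= 1) abort("'fraction' must be in (0, 1)")
  n_remove <- round(nrow(data) * fraction)
  n_subj <- n_distinct(data$subject)
  if (nrow(data) - n_remove < n_subj) {
    abort("fraction too large: removal would empty at least one subject")
  }
  kind <- outcome_kind(data)
  withr::with_seed(seed, {
    repeat {
      drop_idx <- sample.int(nrow(data), n_remove)
      kept <- data[-drop_idx, , drop = FALSE]
      if (n_distinct(kept$subject) == n_subj) break
    }
  })
  as_nested_data(kept, kind)
}

#' Summarise the hierarchical structure of a dataset
#'
#' Counts subjects per group, samples per subject and replicates per sample,
#' and flags whether the design is balanced (equal counts at every level of
#' nesting).
#'
#' @param data A `nested_df`.
#' @return A list with `counts` (tibble of records/samples per subject),
#'   `n_records`, `n_subjects`, `n_groups`, and logical `balanced`.
#' @export
dataset_summary <- function(data) {
  stopifnot(inherits(data, "nested_df"))
  has_sample <- "sample" %in% names(data)
  counts <- data %>%
    group_by(.data$group, .data$subject) %>%
    summarise(
      n_records = n(),
      n_samples = if (has_sample) n_distinct(.data$sample) else n(),
      .groups = "drop"
    )
  per_sample_balanced <- TRUE
  if (has_sample) {
    per_sample <- data %>% count(.data$subject, .data$sample)
    per_sample_balanced <- n_distinct(per_sample$n) == 1L
  }
  balanced <- n_distinct(counts$n_records) == 1L &&
    n_distinct(counts$n_samples) == 1L && per_sample_balanced &&
    n_distinct(count(counts, .data$group)$n) == 1L
  list(
    counts = counts,
    n_records = nrow(data),
    n_subjects = n_distinct(data$subject),
    n_groups = n_distinct(data$group),
    outcome_kind = outcome_kind(data),
    balanced = balanced
  )
}
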
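# Cohort CSV schema and reporting. Two modes share the id/demographic
# columns and differ in the measurement block:
#   raw mode:       measured_length, measured_width, pre_i, pre_s, pre_r,
#                   post_i, post_s, post_r   (photo units)
#   corrected mode: corrected_width, corrected_length, designed_arc,
#                   post_incision            (cm)

raw_measure_cols <- c(
  "measured_length", "measured_width", "pre_i", "pre_s", "pre_r",
  "post_i", "post_s", "post_r"
)
corrected_measure_cols <- c(
  "corrected_width", "corrected_length", "designed_arc", "post_incision"
)

#' Read a cohort CSV
#'
#' Reads a comma-delimited, `.`-decimal, UTF-8 cohort table and validates
#' it. The mode is detected from the header unless given: raw photo
#' measurements or corrected cm lengths. Tables mixing both measurement
#' blocks are rejected, as are unknown body sites and non-positive
#' calibrators; offending rows are named in the error.
#'
#' @param path Path to a CSV file.
#' @param mode `"auto"` (detect from header), `"raw"` or `"corrected"`.
#' @return A validated tibble with a `"cohort_mode"` attribute.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(cohort_sim_config(n_total = 4)), f)
#' read_cohort(f)
read_cohort <- function(path, mode = c("auto", "raw", "corrected")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort_input(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  has_raw <- any(raw_measure_cols %in% names(df))
  has_corr <- any(corrected_measure_cols %in% names(df))
  if (has_raw && has_corr) {
    abort(
      "header mixes raw photo columns and corrected columns; pick one mode",
      class = "fusiform_error_validation"
    )
  }
  detected <- if (has_raw) "raw" else if (has_corr) "corrected" else {
    abort("header matches neither raw nor corrected cohort mode",
      class = "fusiform_error_validation"
    )
  }
  if (mode != "auto" && mode != detected) {
    abort(
      sprintf("file is in %s mode but %s mode was requested", detected, mode),
      class = "fusiform_error_validation"
    )
  }
  need <- if (detected == "raw") raw_measure_cols else corrected_measure_cols
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(
      sprintf(
        "%s-mode file is missing columns: %s",
        detected, paste(missing_cols, collapse = ", ")
      ),
      class = "fusiform_error_validation"
    )
  }
  fail_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      abort(
        sprintf(
          "%s in row(s): %s", what,
          paste(head(rows, 10), collapse = ", ")
        ),
        class = "fusiform_error_validation"
      )
    }
  }
  if ("location" %in% names(df)) {
    fail_rows(
      !is.na(df$location) & !df$location %in% fusiform_sites(),
      "unknown location value"
    )
  }
  if (detected == "raw") {
    for (col in c("pre_s", "pre_r", "post_s", "post_r")) {
      fail_rows(df[[col]] <= 0, sprintf("non-positive calibrator `%s`", col))
    }
    for (col in c("measured_length", "measured_width", "pre_i", "post_i")) {
      fail_rows(df[[col]] < 0, sprintf("negative measurement `%s`", col))
    }
  } else {
    for (col in corrected_measure_cols) {
      fail_rows(df[[col]] <= 0, sprintf("non-positive length `%s`", col))
    }
  }
  attr(df, "cohort_mode") <- detected
  df
}

#' @rdname read_cohort
#' @param records A cohort tibble (either mode).
#' @return `write_cohort()`: `path`, invisibly. Numbers are written at full
#'   double precision so a write/read round trip is lossless.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Render a cohort report
#'
#' Formats a [summarize_by_location()] summary (and optionally paired
#' comparisons) as human-readable tables at 3-decimal display precision
#' alongside a machine-readable JSON document carrying full precision.
#'
#' @param summary A `cohort_summary` object.
#' @param comparisons Optional named list of `paired_comparison` objects.
#' @param path Optional path; if given, the JSON document is written there.
#' @return An object of class `fusiform_report`: list with `text` (character
#'   vector of table lines) and `json` (JSON string).
#' @export
#' @examples
#' cohort <- simulate_cohort() |> compute_model_columns()
#' render_report(summarize_by_location(cohort))
render_report <- function(summary, comparisons = NULL, path = NULL) {
  if (!inherits(summary, "cohort_summary")) {
    abort_input("`summary` must be a `cohort_summary` object")
  }
  txt <- utils::capture.output(print(summary))
  payload <- list(
    n_total = summary$n_total,
    summary = summary$stats |>
      dplyr::mutate(
        location = as.character(.data$location),
        variable = as.character(.data$variable)
      )
  )
  if (!is.null(comparisons)) {
    if (!all(vapply(comparisons, inherits, logical(1), "paired_comparison"))) {
      abort_input("`comparisons` must be a list of `paired_comparison` objects")
    }
    txt <- c(txt, "", unlist(lapply(comparisons, function(cmp) {
      utils::capture.output(print(cmp))
    })))
    payload$comparisons <- lapply(comparisons, function(cmp) {
      unclass(cmp)
    })
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
  }
  structure(list(text = txt, json = json), class = "fusiform_report")
}

#' @export
print.fusiform_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
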
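# Cohort analysis: per-case model evaluation, per-site descriptive
# summaries, and the two paired comparisons that test whether the healed
# incision tracks the designed chord length or the model arc.

model_col_names <- c("model_beta", "model_alpha", "model_theta", "model_arc")

#' Add model-derived columns to a cohort table
#'
#' Evaluates the intersecting-circle model on each case's corrected length
#' and width, appending the apical inner angle (`model_beta`), the apical
#' tangent / central angle (`model_alpha`, `model_theta`, degrees) and the
#' predicted final incision length (`model_arc`, cm).
#'
#' @param records A data frame with positive `corrected_length` and
#'   `corrected_width` columns (cm) and a `case_id` column.
#' @return The input as a tibble with the four model columns appended.
#' @export
#' @examples
#' simulate_cohort(cohort_sim_config(n_total = 5)) |> compute_model_columns()
compute_model_columns <- function(records) {
  for (col in c("corrected_length", "corrected_width")) {
    if (!col %in% names(records)) {
      abort_input(sprintf("`records` must contain a `%s` column", col))
    }
    bad <- !is.finite(records[[col]]) | records[[col]] <= 0
    if (any(bad)) {
      ids <- if ("case_id" %in% names(records)) {
        records$case_id[bad]
      } else {
        which(bad)
      }
      abort(
        sprintf(
          "non-positive or missing `%s` for case(s): %s",
          col, paste(head(ids, 10), collapse = ", ")
        ),
        class = "fusiform_error_validation"
      )
    }
  }
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(
      model_beta = inner_angle(.data$corrected_length, .data$corrected_width),
      model_alpha = 2 * .data$model_beta,
      model_theta = 2 * .data$model_beta,
      model_arc = arc_length(.data$corrected_length, .data$corrected_width)
    )
}

#' Per-site and overall descriptive summary of a cohort
#'
#' Computes mean and sample standard deviation (n - 1 denominator) of the
#' measured and model-derived columns for each body site and for the cohort
#' overall. Sites represented by a single case get SD 0 and are flagged as
#' degenerate.
#'
#' @param records A cohort tibble (corrected mode), typically after
#'   [compute_model_columns()]. Must have a `location` column drawn from
#'   [fusiform_sites()].
#' @param variables Columns to summarise; defaults to whichever of the
#'   standard measurement and model columns are present.
#' @return An object of class `cohort_summary`: a list with `stats` (tibble
#'   of location, n, variable, mean, sd, degenerate), `n_total`, and
#'   `variables`. `location` includes `"overall"`. Use [tidy()] to extract
#'   the tibble.
#' @export
#' @examples
#' simulate_cohort() |>
#'   compute_model_columns() |>
#'   summarize_by_location()
summarize_by_location <- function(records, variables = NULL) {
  if (nrow(records) == 0) {
    abort_input("empty cohort")
  }
  if (!"location" %in% names(records)) {
    abort_input("`records` must contain a `location` column")
  }
  unknown <- setdiff(unique(records$location), fusiform_sites())
  if (length(unknown) > 0) {
    abort(
      sprintf("unknown location value(s): %s", paste(unknown, collapse = ", ")),
      class = "fusiform_error_validation"
    )
  }
  if (is.null(variables)) {
    variables <- intersect(
      c(
        "corrected_width", "corrected_length", "designed_arc", "model_arc",
        "post_incision", "model_beta", "model_alpha"
      ),
      names(records)
    )
  }
  if (length(variables) == 0) {
    abort_input("no summarisable columns found")
  }
  records <- tibble::as_tibble(records)
  records$location <- factor(records$location, levels = fusiform_sites())
  one_block <- function(df, loc) {
    df |>
      tidyr::pivot_longer(
        cols = tidyselect::all_of(variables),
        names_to = "variable", values_to = "value"
      ) |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(
        n = sum(!is.na(.data$value)),
        mean = mean(.data$value, na.rm = TRUE),
        sd = if (sum(!is.na(.data$value)) > 1) {
          sd(.data$value, na.rm = TRUE)
        } else {
          0
        },
        degenerate = sum(!is.na(.data$value)) < 2,
        .groups = "drop"
      ) |>
      dplyr::mutate(location = loc, .before = 1)
  }
  per_site <- records |>
    dplyr::group_split(.data$location) |>
    purrr::map(~ one_block(.x, as.character(.x$location[1]))) |>
    dplyr::bind_rows()
  overall <- one_block(records, "overall")
  stats <- dplyr::bind_rows(per_site, overall) |>
    dplyr::mutate(
      location = factor(.data$location, levels = c(fusiform_sites(), "overall")),
      variable = factor(.data$variable, levels = variables)
    ) |>
    dplyr::arrange(.data$location, .data$variable)
  structure(
    list(stats = stats, n_total = nrow(records), variables = variables),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort summary: %d cases\n", x$n_total))
  wide <- x$stats |>
    dplyr::mutate(
      cell = sprintf(
        "%s (%s)",
        formatC(.data$mean, digits = digits, format = "f"),
        formatC(.data$sd, digits = digits, format = "f")
      )
    ) |>
    dplyr::select("location", "variable", "cell") |>
    tidyr::pivot_wider(names_from = "location", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @describeIn summarize_by_location Tidy the summary into its long-format
#'   statistics tibble.
#' @param x A `cohort_summary` object.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$stats
}

#' @describeIn summarize_by_location One-row overview (total n, number of
#'   sites, number of variables).
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_locations = length(setdiff(unique(as.character(x$stats$location)), "overall")),
    n_variables = length(x$variables)
  )
}

#' Paired comparison of two per-case length columns
#'
#' Two-sided paired t-test plus Pearson correlation between two columns
#' measured on the same incisions -- e.g. the designed chord length versus
#' the healed incision, or the model arc versus the healed incision. Cases
#' with a missing value in either column are dropped pairwise and counted.
#' If the paired differences have zero variance the usual t statistic is
#' undefined and `zero_variance = TRUE` is flagged: the p-value is `NA`
#' when the constant difference is zero (no evidence either way, never
#' silently 1), and 0 when it is nonzero (the difference is exactly
#' constant, `statistic = +-Inf`).
#'
#' @param records A cohort data frame.
#' @param x,y Unquoted column names of the two paired measurements (cm).
#' @param conf_level Confidence level for the mean-difference interval.
#' @return An object of class `paired_comparison` (see [tidy()] /
#'   [glance()] methods) with means, SDs, mean difference, Pearson `r`, the
#'   t statistic and its p-value.
#' @export
#' @examples
#' simulate_cohort() |>
#'   compute_model_columns() |>
#'   compare_paired(model_arc, post_incision)
compare_paired <- function(records, x, y, conf_level = 0.95) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  for (nm in c(x_name, y_name)) {
    if (!nm %in% names(records)) {
      abort_input(sprintf("column `%s` not found in `records`", nm))
    }
  }
  xv <- records[[x_name]]
  yv <- records[[y_name]]
  keep <- !is.na(xv) & !is.na(yv)
  n_dropped <- sum(!keep)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) {
    abort_input("need at least 3 complete pairs")
  }
  d <- xv - yv
  # differences constant to floating precision make the t statistic
  # degenerate (t.test would reject them as "essentially constant")
  zero_var <- sd(d) < 1e-10 * max(abs(mean(xv)), abs(mean(yv)), 1)
  if (zero_var) {
    if (mean(d) == 0) {
      statistic <- NA_real_
      p_value <- NA_real_
    } else {
      statistic <- sign(mean(d)) * Inf
      p_value <- 0
    }
    conf <- c(NA_real_, NA_real_)
  } else {
    tt <- t.test(xv, yv, paired = TRUE, conf.level = conf_level)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
    conf <- as.numeric(tt$conf.int)
  }
  r <- if (sd(xv) == 0 || sd(yv) == 0) NA_real_ else cor(xv, yv)
  structure(
    list(
      x_name = x_name, y_name = y_name, n = n, n_dropped = n_dropped,
      mean_x = mean(xv), sd_x = sd(xv),
      mean_y = mean(yv), sd_y = sd(yv),
      mean_diff = mean(d), sd_diff = sd(d),
      pearson_r = r,
      statistic = statistic, df = n - 1, p_value = p_value,
      conf_low = conf[1], conf_high = conf[2], conf_level = conf_level,
      zero_variance = zero_var
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Paired comparison: %s vs %s (n = %d", x$x_name, x$y_name, x$n))
  if (x$n_dropped > 0) cat(sprintf(", %d incomplete pairs dropped", x$n_dropped))
  cat(")\n")
  cat(sprintf(
    "  %s: %.3f (%.3f)   %s: %.3f (%.3f)\n",
    x$x_name, x$mean_x, x$sd_x, x$y_name, x$mean_y, x$sd_y
  ))
  if (x$zero_variance) {
    cat(sprintf(
      "  mean difference %.3f; zero-variance differences: t-test undefined\n",
      x$mean_diff
    ))
  } else {
    cat(sprintf(
      "  mean difference %.3f, t(%d) = %.3f, p = %.3g\n",
      x$mean_diff, x$df, x$statistic, x$p_value
    ))
  }
  cat(sprintf("  Pearson r = %.3f\n", x$pearson_r))
  invisible(x)
}

#' @describeIn compare_paired One row per comparison with estimates, the t
#'   statistic and p-value (broom layout).
#' @param ... Unused.
#' @export
tidy.paired_comparison <- function(x, ...) {
  obj <- x
  tibble::tibble(
    x = obj$x_name, y = obj$y_name,
    mean_x = obj$mean_x, sd_x = obj$sd_x,
    mean_y = obj$mean_y, sd_y = obj$sd_y,
    estimate = obj$mean_diff,
    pearson_r = obj$pearson_r,
    statistic = obj$statistic,
    df = obj$df,
    p.value = obj$p_value,
    conf.low = obj$conf_low,
    conf.high = obj$conf_high
  )
}

#' @describeIn compare_paired One-row fit overview (n, dropped pairs,
#'   zero-variance flag).
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dropped = x$n_dropped, zero_variance = x$zero_variance,
    conf_level = x$conf_level
  )
}
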
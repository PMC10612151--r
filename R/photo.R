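# Photogrammetric corrections. Raw photo measurements are in arbitrary
# photo units; each photo carries a scale (ruler), read as photo units per
# cm, and a reference object of fixed physical size that appears in both
# the pre- and postoperative photo. The reference ratio corrects the
# altitude (camera-distance) discrepancy between the two photos.

#' Correct a preoperative photo measurement to cm
#'
#' Divides a raw photo measurement by the preoperative scale:
#' `corrected = raw / pre_s`.
#'
#' @param raw Raw measurement, photo units. Vectorised.
#' @param pre_s Preoperative scale, photo units per cm, > 0.
#' @return Length in cm.
#' @export
#' @examples
#' correct_preoperative(3.3, 1.5)
correct_preoperative <- function(raw, pre_s) {
  check_nonnegative_finite(raw, "raw")
  if (!is.numeric(pre_s) || anyNA(pre_s) || any(!is.finite(pre_s)) ||
    any(pre_s <= 0)) {
    abort("`pre_s` must be finite and strictly positive",
      class = "fusiform_error_invalid_calibration"
    )
  }
  a <- recycle_args(raw = raw, pre_s = pre_s)
  a$raw / a$pre_s
}

#' Correct a postoperative photo measurement to cm
#'
#' Applies the altitude-discrepancy correction
#' `corrected = (raw_post * pre_r) / (post_s * post_r)`, where `pre_r` and
#' `post_r` are the raw lengths of the same reference object in the pre- and
#' postoperative photos. When the reference appears equally long in both
#' photos this reduces to the scale-only rule `raw_post / post_s`.
#'
#' @param raw_post Raw postoperative measurement, photo units. Vectorised.
#' @param pre_r,post_r Reference-object raw lengths in the pre- and
#'   postoperative photo, photo units, > 0.
#' @param post_s Postoperative scale, photo units per cm, > 0.
#' @return Length in cm.
#' @export
#' @examples
#' correct_postoperative(5, pre_r = 2, post_s = 4, post_r = 2.5) # 1 cm
correct_postoperative <- function(raw_post, pre_r, post_s, post_r) {
  check_nonnegative_finite(raw_post, "raw_post")
  for (nm in c("pre_r", "post_s", "post_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) == 0L || anyNA(v) ||
      any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("`%s` must be finite and strictly positive", nm),
        class = "fusiform_error_invalid_calibration"
      )
    }
  }
  a <- recycle_args(
    raw_post = raw_post, pre_r = pre_r, post_s = post_s, post_r = post_r
  )
  (a$raw_post * a$pre_r) / (a$post_s * a$post_r)
}

#' Convert a raw-mode photo table into corrected case records
#'
#' Applies [correct_preoperative()] to the measured length, width and
#' one-sided designed incision line (`pre_i`, which becomes the designed
#' arc), and [correct_postoperative()] to the postoperative incision
#' (`post_i`), yielding the corrected-mode cohort table the analysis
#' pipeline consumes. The width, like all preoperative quantities, is
#' corrected with the preoperative scale.
#'
#' @param photos A data frame in raw photo mode: columns `case_id`,
#'   `measured_length`, `measured_width`, `pre_i`, `pre_s`, `pre_r`,
#'   `post_i`, `post_s`, `post_r`, plus any passthrough columns (`age`,
#'   `sex`, `location`, ...).
#' @return A tibble with `corrected_length`, `corrected_width`,
#'   `designed_arc`, `post_incision` (cm) and the passthrough columns.
#' @export
#' @examples
#' photos <- simulate_photo_layer(simulate_cohort(cohort_sim_config(n_total = 5)))
#' correct_photo_measurements(photos)
correct_photo_measurements <- function(photos) {
  need <- c(
    "measured_length", "measured_width", "pre_i", "pre_s", "pre_r",
    "post_i", "post_s", "post_r"
  )
  missing_cols <- setdiff(need, names(photos))
  if (length(missing_cols) > 0) {
    abort_input(sprintf(
      "raw photo table is missing columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  keep <- setdiff(names(photos), need)
  out <- tibble::as_tibble(photos[keep])
  out$corrected_width <- correct_preoperative(photos$measured_width, photos$pre_s)
  out$corrected_length <- correct_preoperative(photos$measured_length, photos$pre_s)
  out$designed_arc <- correct_preoperative(photos$pre_i, photos$pre_s)
  out$post_incision <- correct_postoperative(
    photos$post_i, photos$pre_r, photos$post_s, photos$post_r
  )
  out
}
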
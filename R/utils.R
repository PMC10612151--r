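# Angles are exposed in degrees everywhere (printed clinical convention);
# trigonometry happens in radians. These two helpers are the only place the
# conversion lives.
deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

cot_deg <- function(x) 1 / tan(deg2rad(x))

abort_input <- function(msg, ...) {
  abort(msg, class = "fusiform_error_invalid_input", ...)
}

# Recycle scalar arguments against each other (length-1 against length-n),
# erroring on incompatible lengths. Returns a list of equal-length vectors.
recycle_args <- function(...) {
  args <- list(...)
  ns <- lengths(args)
  n <- max(ns)
  bad <- ns != 1L & ns != n
  if (any(bad)) {
    abort_input(sprintf(
      "arguments `%s` have incompatible lengths (%s)",
      paste(names(args)[bad], collapse = "`, `"),
      paste(ns, collapse = ", ")
    ))
  }
  lapply(args, rep_len, length.out = n)
}

check_positive_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort_input(sprintf("`%s` must be a non-empty numeric vector", name))
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_input(sprintf("`%s` must be finite and strictly positive", name))
  }
  invisible(x)
}

check_nonnegative_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort_input(sprintf("`%s` must be a non-empty numeric vector", name))
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_input(sprintf("`%s` must be finite and non-negative", name))
  }
  invisible(x)
}

#' Body sites recognised by the cohort pipeline
#'
#' The five anatomical locations used throughout the cohort tools, in their
#' canonical order: head, neck, abdomen, upper limbs, lower limbs.
#'
#' @return A character vector of length five.
#' @export
#' @examples
#' fusiform_sites()
fusiform_sites <- function() {
  c("head", "neck", "abdomen", "upper_limbs", "lower_limbs")
}
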
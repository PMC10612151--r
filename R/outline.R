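# Planar realisation of the lens: centroid at the origin, major axis along
# +x, y up, units cm. The upper arc belongs to the circle centred at
# (0, -(r - w/2)) and the lower arc to its mirror image, both of radius r.

#' Planar outline of a fusiform design
#'
#' Samples the two bounding circular arcs into a closed polyline with the
#' vertices exactly at `(+-length/2, 0)` and the width extremes at
#' `(0, +-width/2)`. The polyline perimeter converges to twice the one-sided
#' arc length as `points_per_arc` grows.
#'
#' @inheritParams inner_angle
#' @param points_per_arc Number of sample points per arc (>= 2), endpoints
#'   included.
#' @return A tibble of class `fusiform_outline` with columns `x`, `y`, `side`
#'   (`"upper"`/`"lower"`), ordered counter-clockwise and closed implicitly
#'   (last point joins the first). Attributes: `spec` (named length/width),
#'   `landmarks` (tibble of the points A, B, D, E and the circle centres
#'   O, P).
#' @export
#' @examples
#' out <- fusiform_outline(3, 1)
#' attr(out, "landmarks")
fusiform_outline <- function(length, width, points_per_arc = 256L) {
  check_positive_finite(length, "length")
  check_nonnegative_finite(width, "width")
  if (length(length) != 1L || length(width) != 1L) {
    abort_input("`length` and `width` must be scalars")
  }
  if (points_per_arc < 2) {
    abort_input("`points_per_arc` must be at least 2")
  }
  if (width == 0) {
    warn("width = 0: outline degenerates to the doubled chord")
    pts <- tibble::tibble(
      x = c(-length / 2, length / 2),
      y = c(0, 0),
      side = c("upper", "lower")
    )
    landmarks <- tibble::tibble(
      label = c("A", "B", "D", "E"),
      x = c(-length / 2, length / 2, 0, 0),
      y = 0
    )
  } else {
    r <- circle_radius(length, width)
    half_theta <- deg2rad(tangent_angle(length, width)) / 2
    # Upper arc, centre below the chord; sweep A (left vertex) -> B.
    phi_up <- seq(pi / 2 + half_theta, pi / 2 - half_theta,
      length.out = points_per_arc
    )
    upper <- tibble::tibble(
      x = r * cos(phi_up),
      y = -(r - width / 2) + r * sin(phi_up),
      side = "upper"
    )
    # Lower arc, mirrored; sweep B -> A so the curve closes.
    phi_lo <- seq(-pi / 2 + half_theta, -pi / 2 - half_theta,
      length.out = points_per_arc
    )
    lower <- tibble::tibble(
      x = r * cos(phi_lo),
      y = (r - width / 2) + r * sin(phi_lo),
      side = "lower"
    )
    # Pin the landmarks exactly (the seq endpoints carry ~1e-16 noise).
    upper$x[1] <- -length / 2
    upper$y[1] <- 0
    upper$x[points_per_arc] <- length / 2
    upper$y[points_per_arc] <- 0
    lower$x[1] <- length / 2
    lower$y[1] <- 0
    lower$x[points_per_arc] <- -length / 2
    lower$y[points_per_arc] <- 0
    pts <- dplyr::bind_rows(upper, lower[-1, ])
    pts <- pts[-nrow(pts), ] # drop the duplicated closing vertex A
    landmarks <- tibble::tibble(
      label = c("A", "B", "D", "E", "O", "P"),
      x = c(-length / 2, length / 2, 0, 0, 0, 0),
      y = c(0, 0, width / 2, -width / 2, -(r - width / 2), r - width / 2)
    )
  }
  attr(pts, "spec") <- c(length = length, width = width)
  attr(pts, "landmarks") <- landmarks
  class(pts) <- c("fusiform_outline", class(pts))
  pts
}

#' Perimeter of a closed outline polyline
#'
#' Sums the segment lengths around the closed curve (including the segment
#' joining the last point back to the first).
#'
#' @param outline A [fusiform_outline()] tibble, or any data frame with
#'   `x`, `y` columns describing a closed polyline.
#' @return Perimeter in cm.
#' @export
#' @examples
#' outline_perimeter(fusiform_outline(3, 1, 1e4)) # ~ 2 * arc_length(3, 1)
outline_perimeter <- function(outline) {
  x <- c(outline$x, outline$x[1])
  y <- c(outline$y, outline$y[1])
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Export a printable SVG incision template
#'
#' Writes the outline at true physical scale (1 cm = 10 SVG user units = 10
#' mm under the default 96 dpi-free interpretation stated in the file) with
#' the axis landmarks marked, suitable for printing and sterilisable
#' tracing.
#'
#' @param outline A [fusiform_outline()] object.
#' @param path Output file path (`.svg`).
#' @param margin_cm White margin around the shape, cm.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".svg")
#' write_fusiform_svg(fusiform_outline(3, 1), f)
write_fusiform_svg <- function(outline, path, margin_cm = 0.5) {
  spec <- attr(outline, "spec")
  lm <- attr(outline, "landmarks")
  u <- 10 # user units per cm (1 unit = 1 mm)
  w_cm <- spec[["length"]] + 2 * margin_cm
  h_cm <- max(spec[["width"]], 0.2) + 2 * margin_cm
  # y flipped: SVG y grows downward
  tx <- function(x) (x + w_cm / 2) * u
  ty <- function(y) (h_cm / 2 - y) * u
  pts <- paste(
    sprintf("%.4f,%.4f", tx(outline$x), ty(outline$y)),
    collapse = " "
  )
  marks <- lm[lm$label %in% c("A", "B", "D", "E"), , drop = FALSE]
  mark_svg <- paste(
    sprintf(
      paste0(
        '<circle cx="%.4f" cy="%.4f" r="0.6" fill="black"/>',
        '<text x="%.4f" y="%.4f" font-size="3" font-family="sans-serif">%s</text>'
      ),
      tx(marks$x), ty(marks$y), tx(marks$x) + 1, ty(marks$y) - 1, marks$label
    ),
    collapse = "\n  "
  )
  svg <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<svg xmlns="http://www.w3.org/2000/svg" width="%.2fmm" height="%.2fmm" ',
      'viewBox="0 0 %.4f %.4f">\n',
      "  <!-- incision template: 1 cm = 10 user units (printed at 1 unit = 1 mm); ",
      "length %.3f cm, width %.3f cm -->\n",
      '  <polygon points="%s" fill="none" stroke="black" stroke-width="0.3"/>\n',
      "  %s\n",
      "</svg>\n"
    ),
    w_cm * u, h_cm * u, w_cm * u, h_cm * u,
    spec[["length"]], spec[["width"]], pts, mark_svg
  )
  writeLines(svg, path)
  invisible(path)
}

#' Plot a fusiform outline
#'
#' @param object A [fusiform_outline()] object.
#' @param ... Unused.
#' @return A ggplot with equal coordinates, the closed outline and the
#'   vertex/width landmarks.
#' @export
autoplot.fusiform_outline <- function(object, ...) {
  lm <- attr(object, "landmarks")
  lm <- lm[lm$label %in% c("A", "B", "D", "E"), , drop = FALSE]
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(fill = NA, colour = "black") +
    ggplot2::geom_point(data = lm, colour = "red") +
    ggplot2::geom_text(
      data = lm, ggplot2::aes(label = .data$label),
      nudge_x = 0.04, nudge_y = 0.04, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot the dimensionless design curves
#'
#' @param object A [design_curves()] tibble.
#' @param ... Unused.
#' @return A ggplot of `a/w`, `l/w` and `e/w` against the apical inner
#'   angle.
#' @export
autoplot.fusiform_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("ratio_a_w", "ratio_l_w", "ratio_e_w"),
    names_to = "ratio", values_to = "value"
  )
  long$ratio <- factor(
    long$ratio,
    levels = c("ratio_a_w", "ratio_l_w", "ratio_e_w"),
    labels = c("a/w", "l/w", "e/w")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$inner_angle, .data$value,
    colour = .data$ratio
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "apical inner angle (degrees)", y = "ratio",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
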
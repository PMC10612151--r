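# Forward model of the equal-diameter intersecting-circle fusiform.
#
# Two identical circles of radius r intersect at the vertices A and B of the
# lens. The chord AB is the fusiform length l; the segment DE across the
# middle is the width w (each arc's sagitta is w/2). Three angles describe
# the vertex: the apical inner angle beta (angle DAE), the apical tangent
# angle alpha (between the circles' tangents at a vertex), and the central
# angle theta (angle AOB at one circle's centre). They satisfy
# theta = alpha = 2 * beta identically.

#' Apical inner angle of a fusiform from its length and width
#'
#' For a fusiform (lens) bounded by two identical circular arcs with chord
#' (length) `l` and total width `w`, the apical inner angle -- the angle at a
#' vertex subtended by the two width endpoints -- is
#' \deqn{\beta = 2\,\arctan(w/l).}
#'
#' @param length Fusiform length (chord between the vertices), cm. Vectorised.
#' @param width Fusiform width (minor axis), cm. Vectorised.
#' @return Inner angle in degrees, in (0, 180). Values exceed 90 degrees only
#'   for non-canonical designs with `width > length`.
#' @seealso [tangent_angle()], [length_from_inner_angle()] for the inverse.
#' @export
#' @examples
#' inner_angle(3, 1)     # ~36.87 degrees
#' inner_angle(1, 1)     # 90 degrees: the lens is a full circle
inner_angle <- function(length, width) {
  check_positive_finite(length, "length")
  check_positive_finite(width, "width")
  a <- recycle_args(length = length, width = width)
  rad2deg(2 * atan(a$width / a$length))
}

#' Tangent and central angles from the apical inner angle
#'
#' In the intersecting-circle model the central angle equals the apical
#' tangent angle, and both are twice the apical inner angle:
#' \eqn{\theta = \alpha = 2\beta}. `angle_relations()` returns all three;
#' `tangent_angle()` is the direct length/width form
#' \eqn{\alpha = 4\arctan(w/l)}.
#'
#' @param beta Apical inner angle in degrees, in (0, 180).
#' @return `angle_relations()`: a tibble with columns `inner_angle`,
#'   `tangent_angle`, `central_angle` (degrees). `tangent_angle()`: the
#'   tangent angle in degrees.
#' @export
#' @examples
#' angle_relations(50.366)  # tangent/central angle 100.732
#' tangent_angle(3, 1)      # ~73.74, the "74 degree" vertex at ratio 3:1
angle_relations <- function(beta) {
  check_positive_finite(beta, "beta")
  if (any(beta >= 180)) {
    abort_input("`beta` must lie in (0, 180) degrees")
  }
  tibble::tibble(
    inner_angle = beta,
    tangent_angle = 2 * beta,
    central_angle = 2 * beta
  )
}

#' @rdname angle_relations
#' @inheritParams inner_angle
#' @export
tangent_angle <- function(length, width) {
  2 * inner_angle(length, width)
}

#' Fusiform length from a target apical inner angle
#'
#' Inverts the angle relation: a fusiform of width `w` whose apical inner
#' angle is \eqn{\beta} has length \eqn{l = \cot(\beta/2)\,w}. Designs with
#' `beta <= 90` degrees are the canonical regime (`length >= width`).
#'
#' @param beta Apical inner angle, degrees, in (0, 180).
#' @param width Fusiform width, cm.
#' @return Length in cm.
#' @export
#' @examples
#' length_from_inner_angle(15, 1)  # ~7.60: a 30-degree tangent angle needs 7.6:1
#' length_from_inner_angle(90, 1)  # 1: the circular lens
length_from_inner_angle <- function(beta, width) {
  check_positive_finite(beta, "beta")
  check_positive_finite(width, "width")
  if (any(beta >= 180)) {
    abort_input("`beta` must lie in (0, 180) degrees")
  }
  a <- recycle_args(beta = beta, width = width)
  cot_deg(a$beta / 2) * a$width
}

#' Radius of the generating circles
#'
#' Chord--sagitta relation for one bounding arc: with chord `l` and sagitta
#' `w/2`, the circle radius is \eqn{r = (l^2 + w^2)/(4w)}.
#'
#' @inheritParams inner_angle
#' @return Radius in cm.
#' @export
#' @examples
#' circle_radius(3, 1)  # 2.5 = 5 * (w/2): radius is 5x the semi-minor axis
circle_radius <- function(length, width) {
  check_positive_finite(length, "length")
  if (is.numeric(width) && length(width) > 0 && !anyNA(width) && any(width == 0)) {
    abort("`width` = 0 gives an infinite radius (degenerate fusiform)",
      class = "fusiform_error_infinite_radius"
    )
  }
  check_positive_finite(width, "width")
  a <- recycle_args(length = length, width = width)
  (a$length^2 + a$width^2) / (4 * a$width)
}

#' Arc length of one side of the fusiform
#'
#' Length of one bounding circular arc from vertex to vertex,
#' \eqn{a = r\,\theta} with \eqn{\theta} in radians; equivalently
#' \deqn{a = \frac{\beta}{360^\circ}\,\pi\,\bigl(1 + \cot^2(\beta/2)\bigr)\,w.}
#' Under the model the healed (postoperative) incision length equals this
#' arc, not the designed chord length.
#'
#' @inheritParams inner_angle
#' @return Arc length in cm. Always at least `length`, and at least
#'   \eqn{\pi w / 2} divided by ... see `arc_width_ratio()`; the ratio `a/w`
#'   attains its minimum \eqn{\pi/2} at `length == width`.
#' @export
#' @examples
#' arc_length(1, 1)  # pi/2: semicircle of radius 1/2
#' arc_length(3, 1)  # ~3.218
arc_length <- function(length, width) {
  theta_rad <- deg2rad(tangent_angle(length, width))
  circle_radius(length, width) * theta_rad
}

#' @rdname arc_length
#' @param beta Apical inner angle, degrees, in (0, 180).
#' @return `arc_width_ratio()`: the dimensionless ratio `a/w` as a function
#'   of the inner angle.
#' @export
arc_width_ratio <- function(beta) {
  check_positive_finite(beta, "beta")
  if (any(beta >= 180)) {
    abort_input("`beta` must lie in (0, 180) degrees")
  }
  (beta / 360) * pi * (1 + cot_deg(beta / 2)^2)
}

#' Vertex push-out distance
#'
#' When the wound closes along the arc, each designed vertex is pushed
#' outward along the major axis by \eqn{e = (a - l)/2}, half the excess of
#' the arc over the chord. The predicted final incision runs from
#' \eqn{-l/2 - e} to \eqn{l/2 + e}.
#'
#' @inheritParams inner_angle
#' @return Push-out distance in cm (non-negative; 0 only in the flat limit
#'   `width -> 0`).
#' @export
#' @examples
#' pushout_distance(1, 1)  # (pi/2 - 1)/2
#' pushout_distance(3, 1)  # ~0.109
pushout_distance <- function(length, width) {
  a <- recycle_args(length = length, width = width)
  (arc_length(a$length, a$width) - a$length) / 2
}

#' Recover the inner angle from an arc-to-width ratio
#'
#' Numerically inverts the strictly decreasing map \eqn{\beta \mapsto a/w}
#' on the canonical design domain \eqn{\beta \in (0, 90]} degrees. The ratio
#' attains its minimum \eqn{\pi/2} at \eqn{\beta = 90} (the circular lens),
#' so ratios below \eqn{\pi/2} are infeasible.
#'
#' @param rho Target arc-to-width ratio `a/w`, dimensionless,
#'   \eqn{\ge \pi/2}. Vectorised.
#' @param tol Absolute tolerance on the returned angle, degrees.
#' @return Inner angle in degrees, in (0, 90].
#' @export
#' @examples
#' invert_arc_width_ratio(pi / 2)                 # 90 degrees exactly
#' invert_arc_width_ratio(arc_width_ratio(50))    # round trip: 50
invert_arc_width_ratio <- function(rho, tol = 1e-10) {
  check_positive_finite(rho, "rho")
  if (any(rho < pi / 2 - 1e-12)) {
    abort(
      sprintf(
        "arc-to-width ratio below the feasible minimum pi/2 = %.6f",
        pi / 2
      ),
      class = "fusiform_error_infeasible_ratio"
    )
  }
  vapply(rho, function(r) {
    if (r <= pi / 2) {
      return(90)
    }
    lo <- 45
    while (arc_width_ratio(lo) < r) lo <- lo / 2
    uniroot(
      function(b) arc_width_ratio(b) - r,
      interval = c(lo, 90), tol = tol
    )$root
  }, numeric(1))
}

#' Full derived geometry of one or more fusiform designs
#'
#' Evaluates every model quantity for each (length, width) pair: the three
#' vertex angles, circle radius, one-sided arc length (the predicted final
#' incision length), vertex push-out distance, and the dimensionless design
#' ratios. Canonical designs have `length >= width` (inner angle at most 90
#' degrees); wider-than-long lenses are computed but flagged.
#'
#' @inheritParams inner_angle
#' @return A tibble of class `fusiform_geometry` with one row per design and
#'   columns `length`, `width`, `inner_angle`, `tangent_angle`,
#'   `central_angle` (degrees), `radius`, `arc`, `pushout` (cm),
#'   `ratio_l_w`, `ratio_a_w`, `ratio_e_w`, and logical `canonical`.
#' @export
#' @examples
#' fusiform_geometry(3, 1)
#' fusiform_geometry(length = c(1, 2, 3), width = 1)
fusiform_geometry <- function(length, width) {
  a <- recycle_args(length = length, width = width)
  beta <- inner_angle(a$length, a$width)
  arc <- arc_length(a$length, a$width)
  out <- tibble::tibble(
    length = a$length,
    width = a$width,
    inner_angle = beta,
    tangent_angle = 2 * beta,
    central_angle = 2 * beta,
    radius = circle_radius(a$length, a$width),
    arc = arc,
    pushout = (arc - a$length) / 2,
    ratio_l_w = a$length / a$width,
    ratio_a_w = arc / a$width,
    ratio_e_w = (arc - a$length) / (2 * a$width),
    canonical = a$length >= a$width
  )
  class(out) <- c("fusiform_geometry", class(out))
  out
}

#' Dimensionless design curves over a grid of inner angles
#'
#' Tabulates the three design ratios -- arc/width (`a/w`), length/width
#' (`l/w`) and push-out/width (`e/w`) -- as functions of the apical inner
#' angle on the canonical domain (0, 90] degrees. `a/w` and `l/w` decrease
#' strictly with the angle while `e/w` increases, and
#' `a/w - l/w = 2 e/w` at every point.
#'
#' @param beta Grid of inner angles, degrees, each in (0, 90].
#' @return A tibble of class `fusiform_curves` with columns `inner_angle`,
#'   `ratio_a_w`, `ratio_l_w`, `ratio_e_w`.
#' @seealso [autoplot.fusiform_curves()] to plot the three curves.
#' @export
#' @examples
#' design_curves(seq(10, 90, by = 10))
design_curves <- function(beta) {
  check_positive_finite(beta, "beta")
  if (any(beta > 90)) {
    abort_input("design curves are defined on the canonical domain (0, 90] degrees")
  }
  lw <- cot_deg(beta / 2)
  aw <- arc_width_ratio(beta)
  out <- tibble::tibble(
    inner_angle = beta,
    ratio_a_w = aw,
    ratio_l_w = lw,
    ratio_e_w = (aw - lw) / 2
  )
  class(out) <- c("fusiform_curves", class(out))
  out
}
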
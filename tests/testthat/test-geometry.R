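test_that("angle relations and printed landmark values hold", {
  # circular lens: l = w gives a 90-degree inner angle
  expect_equal(inner_angle(1, 1), 90)
  # 3:1 design: the classic 74-degree vertex (tangent) angle
  expect_equal(round(tangent_angle(3, 1)), 74)
  expect_equal(inner_angle(3, 1), 2 * atan(1 / 3) * 180 / pi, tolerance = 1e-12)
  # high-precision inner angle at the cohort's mean ratio 2.18
  expect_equal(inner_angle(2.18, 1), 49.2833239991167, tolerance = 1e-10)

  rel <- angle_relations(c(15, 50.366, 90))
  expect_equal(rel$tangent_angle, c(30, 100.732, 180))
  expect_equal(rel$central_angle, rel$tangent_angle)
  expect_equal(rel$inner_angle * 2, rel$tangent_angle)
})

test_that("length from inner angle matches cot(beta/2) * w and round-trips", {
  # a 30-degree tangent angle (inner 15) needs a 7.6:1 design
  expect_equal(round(length_from_inner_angle(15, 1), 1), 7.6)
  expect_equal(length_from_inner_angle(15, 1), 7.59575411272515, tolerance = 1e-10)
  expect_equal(length_from_inner_angle(90, 1), 1)
  expect_equal(length_from_inner_angle(36.8698976458440, 2), 6, tolerance = 1e-9)

  beta <- seq(5, 90, by = 0.5)
  l <- length_from_inner_angle(beta, 1)
  expect_equal(inner_angle(l, 1), beta, tolerance = 1e-9)
})

test_that("circle radius obeys the chord-sagitta relation", {
  expect_equal(circle_radius(3, 1), 2.5) # 5x the semi-minor axis w/2
  expect_equal(circle_radius(1, 1), 0.5)
  expect_equal(circle_radius(4, 1), 17 / 4)
  expect_error(circle_radius(3, 0), class = "fusiform_error_infinite_radius")

  withr::with_seed(11, {
    sp <- random_specs(100)
    r <- circle_radius(sp$length, sp$width)
    lhs <- (sp$length / 2)^2 + (r - sp$width / 2)^2
    expect_equal(lhs / r^2, rep(1, 100), tolerance = 1e-12)
  })
})

test_that("arc length matches frozen values and its defining limits", {
  expect_equal(arc_length(1, 1), pi / 2, tolerance = 1e-14)
  expect_equal(arc_length(3, 1), 3.21750554396642, tolerance = 1e-12)
  # flat limit: arc degenerates to the chord
  expect_equal(arc_length(2, 1e-7), 2, tolerance = 1e-9)
  # arc formula in beta agrees with r * theta
  beta <- inner_angle(3, 1)
  expect_equal(arc_width_ratio(beta), arc_length(3, 1), tolerance = 1e-12)
})

test_that("push-out distance is half the arc excess over the chord", {
  expect_equal(pushout_distance(1, 1), (pi / 2 - 1) / 2, tolerance = 1e-14)
  expect_equal(pushout_distance(3, 1), 0.108752771983211, tolerance = 1e-12)
  expect_equal(pushout_distance(2, 1e-7), 0, tolerance = 1e-7)
  withr::with_seed(21, {
    sp <- random_specs(100)
    g <- fusiform_geometry(sp$length, sp$width)
    expect_true(all(g$arc >= g$length))
    expect_true(all(g$pushout >= 0))
    expect_equal(g$pushout, (g$arc - g$length) / 2, tolerance = 1e-14)
  })
})

test_that("arc-width ratio inversion recovers the inner angle uniquely", {
  expect_equal(invert_arc_width_ratio(pi / 2), 90)
  expect_equal(invert_arc_width_ratio(arc_width_ratio(50)), 50, tolerance = 1e-8)
  # consistency with the l/w = 3 forward case (w = 1 so rho = a)
  expect_equal(
    invert_arc_width_ratio(3.21750554396642),
    inner_angle(3, 1),
    tolerance = 1e-6
  )
  beta <- seq(5, 90, by = 2.5)
  expect_equal(
    invert_arc_width_ratio(arc_width_ratio(beta)), beta,
    tolerance = 1e-8
  )
  expect_error(invert_arc_width_ratio(1.2), class = "fusiform_error_infeasible_ratio")
})

test_that("design curves are monotone and internally consistent", {
  grid <- seq(1, 90, length.out = 500)
  dc <- design_curves(grid)
  expect_true(all(diff(dc$ratio_a_w) < 0))
  expect_true(all(diff(dc$ratio_l_w) < 0))
  expect_true(all(diff(dc$ratio_e_w) > 0))
  expect_equal(dc$ratio_a_w - dc$ratio_l_w, 2 * dc$ratio_e_w, tolerance = 1e-12)
  # the a/w minimum pi/2 sits at the circular lens
  expect_equal(dc$ratio_a_w[length(grid)], pi / 2, tolerance = 1e-12)
  last <- design_curves(90)
  expect_equal(last$ratio_l_w, 1)
  expect_equal(last$ratio_e_w, (pi / 2 - 1) / 2, tolerance = 1e-12)
  expect_error(design_curves(c(10, 95)), class = "fusiform_error_invalid_input")
})

test_that("invalid design parameters are rejected", {
  expect_error(inner_angle(-1, 1), class = "fusiform_error_invalid_input")
  expect_error(inner_angle(1, 0), class = "fusiform_error_invalid_input")
  expect_error(angle_relations(200), class = "fusiform_error_invalid_input")
  expect_error(length_from_inner_angle(180, 1), class = "fusiform_error_invalid_input")
  expect_error(arc_length(NA_real_, 1), class = "fusiform_error_invalid_input")
})

test_that("fusiform_geometry flags non-canonical wider-than-long designs", {
  g <- fusiform_geometry(c(3, 1, 0.5), c(1, 1, 1))
  expect_equal(g$canonical, c(TRUE, TRUE, FALSE))
  expect_true(all(g$inner_angle[g$canonical] <= 90))
  expect_gt(g$inner_angle[3], 90)
  # recycling of a scalar width
  g2 <- fusiform_geometry(c(2, 3), 1)
  expect_equal(g2$width, c(1, 1))
})

test_that("analytic arc length matches an independent polyline oracle", {
  withr::with_seed(31, {
    sp <- random_specs(20)
    a <- arc_length(sp$length, sp$width)
    oracle <- mapply(polyline_arc_oracle, sp$length, sp$width,
      MoreArgs = list(n_segments = 1e4)
    )
    # 1e4 segments: discretization error ~ (theta/n)^2 / 24, well below 1e-7
    expect_equal(a, oracle, tolerance = 1e-7)
  })
})
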
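test_that("model columns match scalar geometry calls case by case", {
  rec <- tibble::tibble(
    case_id = c("a", "b", "c"),
    location = c("head", "neck", "abdomen"),
    corrected_length = c(1, 3, 2.18),
    corrected_width = c(1, 1, 1)
  )
  m <- compute_model_columns(rec)
  expect_equal(m$model_beta, inner_angle(rec$corrected_length, 1))
  expect_equal(m$model_alpha, 2 * m$model_beta)
  expect_equal(m$model_theta, m$model_alpha)
  expect_equal(m$model_arc, arc_length(rec$corrected_length, 1))
  expect_equal(m$model_beta[1], 90)
  expect_equal(m$model_arc[1], pi / 2, tolerance = 1e-14)
  expect_equal(round(m$model_alpha[2]), 74) # classic 3:1 vertex angle
})

test_that("invalid case measurements fail with the offending case ids", {
  rec <- tibble::tibble(
    case_id = c("ok", "bad_zero", "bad_na"),
    corrected_length = c(1, 0, 2),
    corrected_width = c(0.5, 0.5, NA)
  )
  expect_error(
    compute_model_columns(rec),
    regexp = "bad_zero",
    class = "fusiform_error_validation"
  )
  ok <- tibble::tibble(case_id = "a", corrected_length = 1)
  expect_error(
    compute_model_columns(ok),
    class = "fusiform_error_invalid_input"
  )
})

test_that("per-site summaries use sample SDs and flag degenerate groups", {
  rec <- tiny_cohort()
  s <- summarize_by_location(rec)
  st <- tidy(s)
  ov <- st[st$location == "overall", ]
  # widths 0.4..0.8: mean 0.6, sample sd sqrt(0.025)
  expect_equal(ov$mean[ov$variable == "corrected_width"], 0.6)
  expect_equal(
    ov$sd[ov$variable == "corrected_width"], 0.158113883008419,
    tolerance = 1e-12
  )
  expect_equal(ov$mean[ov$variable == "corrected_length"], 1.5)
  expect_equal(ov$n[ov$variable == "corrected_length"], 5)
  # head widths 0.4, 0.5, 0.8: hand-computed
  hd <- st[st$location == "head" & st$variable == "corrected_width", ]
  expect_equal(hd$mean, mean(c(0.4, 0.5, 0.8)))
  expect_equal(hd$sd, 0.208166599946613, tolerance = 1e-12)
  # single-case sites: SD reported 0 and flagged degenerate
  nk <- st[st$location == "neck" & st$variable == "corrected_width", ]
  expect_equal(nk$sd, 0)
  expect_true(nk$degenerate)
  expect_false(hd$degenerate)
  # overall n equals the sum over sites
  per_site <- st[st$location != "overall" & st$variable == "corrected_width", ]
  expect_equal(sum(per_site$n), s$n_total)
  g <- glance(s)
  expect_equal(g$n_total, 5)
  expect_equal(g$n_locations, 3)
})

test_that("summaries reject empty cohorts and unknown sites", {
  expect_error(summarize_by_location(tiny_cohort()[0, ]),
    class = "fusiform_error_invalid_input"
  )
  bad <- tiny_cohort()
  bad$location[2] <- "torso"
  expect_error(summarize_by_location(bad), class = "fusiform_error_validation")
})

test_that("paired comparison handles identical and exactly shifted columns", {
  rec <- tibble::tibble(a = seq(1, 2, length.out = 10))
  rec$b <- rec$a
  same <- compare_paired(rec, a, b)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$pearson_r, 1)
  expect_true(same$zero_variance)
  expect_true(is.na(same$p_value))

  rec$c <- rec$a + 0.3
  shifted <- compare_paired(rec, a, c)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$mean_diff, -0.3)
  expect_true(shifted$zero_variance)
  expect_lt(shifted$p_value, 0.05)
})

test_that("paired comparison matches t.test/cor and tidies to one row", {
  withr::with_seed(42, {
    rec <- tibble::tibble(x = runif(30, 1, 3))
    rec$y <- rec$x * 1.1 + rnorm(30, 0, 0.05)
  })
  cmp <- compare_paired(rec, x, y)
  tt <- t.test(rec$x, rec$y, paired = TRUE)
  expect_equal(cmp$p_value, tt$p.value)
  expect_equal(cmp$statistic, unname(tt$statistic))
  expect_equal(cmp$pearson_r, cor(rec$x, rec$y))
  td <- tidy(cmp)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, mean(rec$x - rec$y))
  expect_equal(td$p.value, tt$p.value)
  expect_equal(glance(cmp)$n, 30)
})

test_that("Pearson r is invariant to affine rescaling of either column", {
  withr::with_seed(7, {
    rec <- tibble::tibble(x = runif(25), y = runif(25))
  })
  r0 <- compare_paired(rec, x, y)$pearson_r
  rec$x2 <- 3.2 * rec$x + 1.7
  expect_equal(compare_paired(rec, x2, y)$pearson_r, r0, tolerance = 1e-12)
})

test_that("incomplete pairs are dropped pairwise and counted", {
  rec <- tiny_cohort()
  rec$post_incision[2] <- NA
  cmp <- compare_paired(rec, designed_arc, post_incision)
  expect_equal(cmp$n, 4)
  expect_equal(cmp$n_dropped, 1)
  expect_error(
    compare_paired(rec[1:2, ], designed_arc, post_incision),
    class = "fusiform_error_invalid_input"
  )
})
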
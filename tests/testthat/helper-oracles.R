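# Independent numeric oracle for the one-sided arc length: discretize the
# bounding circle directly from the chord-sagitta construction and sum the
# chord lengths of the discretization. Shares nothing with arc_length()
# beyond the definition of the circle.
polyline_arc_oracle <- function(length, width, n_segments = 1e6) {
  r <- (length^2 + width^2) / (4 * width)
  half_theta <- asin((length / 2) / r)
  # the centre sits below the chord when the sagitta w/2 < r
  if (width / 2 > r) half_theta <- pi - half_theta
  phi <- seq(pi / 2 - half_theta, pi / 2 + half_theta,
    length.out = n_segments + 1
  )
  x <- r * cos(phi)
  y <- r * sin(phi)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Random canonical design specs, reproducible under the caller's seed.
random_specs <- function(n) {
  width <- runif(n, 0.1, 3)
  ratio <- runif(n, 1, 8)
  data.frame(length = ratio * width, width = width)
}

# Minimal corrected-mode cohort fixture with easy hand-checked numbers.
tiny_cohort <- function() {
  tibble::tibble(
    case_id = sprintf("case_%02d", 1:5),
    age = c(30, 40, 50, 60, 70),
    sex = c("female", "male", "female", "male", "female"),
    location = c("head", "head", "neck", "abdomen", "head"),
    corrected_width = c(0.4, 0.5, 0.6, 0.7, 0.8),
    corrected_length = c(1.0, 1.2, 1.5, 1.8, 2.0),
    designed_arc = c(1.1, 1.3, 1.6, 1.9, 2.2),
    post_incision = c(1.12, 1.33, 1.58, 1.95, 2.18)
  )
}
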
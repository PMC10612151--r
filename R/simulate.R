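# Seeded synthetic cohorts with the structure the clinical study assumes:
# a five-site mix, site-specific width distributions, a shared
# length-to-width ratio distribution, a hand-drawn designed incision line
# equal to the model arc plus additive drawing noise, and a healed incision
# equal to the model arc times multiplicative biological/measurement noise.

# Inverse-CDF sampler for a normal truncated to [lower, upper]; sd = 0
# degenerates to the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (length(mean) == 1L) mean <- rep_len(mean, n)
  if (length(sd) == 1L) sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- sd > 0
  if (any(pos)) {
    plo <- pnorm(lower, mean[pos], sd[pos])
    phi <- pnorm(upper, mean[pos], sd[pos])
    out[pos] <- qnorm(runif(sum(pos), plo, phi), mean[pos], sd[pos])
  }
  out[!pos] <- pmin(pmax(mean[!pos], lower), upper)
  out
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the descriptive structure of the 101-case clinical
#' cohort the model was validated on: the site mix (66 head, 6 neck, 11
#' abdomen, 13 upper limbs, 5 lower limbs), per-site preoperative width
#' mean/SD, a length-to-width ratio of 2.18 +- 0.39 shared across sites, and
#' the demographic margins (age 37.0 +- 14.5 years, 57.4% female).
#'
#' @param n_total Number of cases.
#' @param site_mix Named numeric vector of proportions (or counts, which are
#'   normalised) over [fusiform_sites()].
#' @param width_mean,width_sd Named per-site mean and SD of the preoperative
#'   width, cm.
#' @param ratio_mean,ratio_sd Mean and SD of the length-to-width ratio.
#' @param ratio_floor Lower truncation of the ratio (designs narrower than
#'   this are not drawn in practice).
#' @param width_floor Lower truncation of the width, cm.
#' @param design_noise_sd Additive SD of the hand-drawn designed incision
#'   line around the model arc, cm.
#' @param post_noise_cv Coefficient of variation of the multiplicative noise
#'   on the healed incision around the model arc.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal), years.
#' @param prop_female Proportion of female cases.
#' @param seed Integer seed governing the whole cohort draw.
#' @return A validated list of class `cohort_sim_config`.
#' @export
#' @examples
#' cohort_sim_config(n_total = 20, seed = 42)
cohort_sim_config <- function(n_total = 101L,
                              site_mix = c(
                                head = 66, neck = 6, abdomen = 11,
                                upper_limbs = 13, lower_limbs = 5
                              ),
                              width_mean = c(
                                head = 0.565, neck = 0.650, abdomen = 0.726,
                                upper_limbs = 0.702, lower_limbs = 0.702
                              ),
                              width_sd = c(
                                head = 0.175, neck = 0.182, abdomen = 0.290,
                                upper_limbs = 0.232, lower_limbs = 0.361
                              ),
                              ratio_mean = 2.18,
                              ratio_sd = 0.39,
                              ratio_floor = 1.05,
                              width_floor = 0.05,
                              design_noise_sd = 0.05,
                              post_noise_cv = 0.05,
                              age_mean = 37.0,
                              age_sd = 14.5,
                              age_range = c(1, 95),
                              prop_female = 0.574,
                              seed = 1L) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1 ||
    n_total != round(n_total)) {
    abort_input("`n_total` must be a positive integer")
  }
  sites <- fusiform_sites()
  for (nm in c("site_mix", "width_mean", "width_sd")) {
    v <- get(nm)
    if (!all(sites %in% names(v))) {
      abort_input(sprintf("`%s` must be named over all five sites", nm))
    }
  }
  if (any(site_mix < 0) || sum(site_mix) <= 0) {
    abort_input("`site_mix` must be non-negative with a positive sum")
  }
  site_mix <- site_mix[sites] / sum(site_mix[sites])
  check_positive_finite(width_mean, "width_mean")
  check_nonnegative_finite(width_sd, "width_sd")
  check_positive_finite(ratio_mean, "ratio_mean")
  check_nonnegative_finite(ratio_sd, "ratio_sd")
  check_nonnegative_finite(design_noise_sd, "design_noise_sd")
  check_nonnegative_finite(post_noise_cv, "post_noise_cv")
  if (ratio_floor < 1) {
    abort_input("`ratio_floor` below 1 would allow wider-than-long designs")
  }
  if (prop_female < 0 || prop_female > 1) {
    abort_input("`prop_female` must lie in [0, 1]")
  }
  structure(
    list(
      n_total = as.integer(n_total), site_mix = site_mix,
      width_mean = width_mean[sites], width_sd = width_sd[sites],
      ratio_mean = ratio_mean, ratio_sd = ratio_sd,
      ratio_floor = ratio_floor, width_floor = width_floor,
      design_noise_sd = design_noise_sd, post_noise_cv = post_noise_cv,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      prop_female = prop_female, seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate a synthetic excision cohort
#'
#' Draws `n_total` cases: a body site from the configured mix, a
#' preoperative width from that site's truncated normal, a length equal to
#' width times a truncated-normal length-to-width ratio, the model arc for
#' that design, a designed (hand-drawn) incision line equal to the arc plus
#' additive noise, and a healed incision equal to the arc times
#' `1 + N(0, post_noise_cv)`. The draw is fully determined by
#' `config$seed`.
#'
#' @param config A [cohort_sim_config()].
#' @return A corrected-mode cohort tibble: `case_id`, `age`, `sex`,
#'   `location`, `corrected_width`, `corrected_length`, `designed_arc`,
#'   `post_incision` (cm).
#' @export
#' @examples
#' simulate_cohort(cohort_sim_config(seed = 7))
simulate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    abort_input("`config` must be a `cohort_sim_config()`")
  }
  n <- config$n_total
  withr::with_seed(config$seed, {
    location <- sample(fusiform_sites(), n, replace = TRUE, prob = config$site_mix)
    width <- rtruncnorm(
      n,
      mean = config$width_mean[location], sd = config$width_sd[location],
      lower = config$width_floor
    )
    ratio <- rtruncnorm(
      n,
      mean = config$ratio_mean, sd = config$ratio_sd,
      lower = config$ratio_floor
    )
    len <- ratio * width
    arc <- arc_length(len, width)
    designed_arc <- pmax(arc + rnorm(n, 0, config$design_noise_sd), 0.01)
    post <- arc * (1 + rnorm(n, 0, config$post_noise_cv))
    age <- round(rtruncnorm(
      n, config$age_mean, config$age_sd,
      lower = config$age_range[1], upper = config$age_range[2]
    ))
    sex <- ifelse(runif(n) < config$prop_female, "female", "male")
  })
  tibble::tibble(
    case_id = sprintf("case_%04d", seq_len(n)),
    age = age,
    sex = sex,
    location = location,
    corrected_width = width,
    corrected_length = len,
    designed_arc = designed_arc,
    post_incision = post
  )
}

#' Embed a cohort's true lengths into raw photo measurements
#'
#' The inverse of the photo-correction step, for end-to-end testing: each
#' case gets jittered pre- and postoperative photo scales and
#' reference-object readings, and the raw measurements are constructed so
#' that [correct_photo_measurements()] recovers the input cm lengths
#' exactly. The postoperative reference is additionally jittered relative
#' to its scale, emulating an altitude discrepancy between the two photos.
#'
#' @param records A corrected-mode cohort tibble (e.g. from
#'   [simulate_cohort()]).
#' @param scale_jitter SD of the log-normal jitter applied to scales and
#'   references (0 = all photos at unit scale).
#' @param ref_length Physical length of the reference object, cm.
#' @param seed Integer seed for the jitter draw.
#' @return A raw-mode photo tibble (columns `measured_length`,
#'   `measured_width`, `pre_i`, `pre_s`, `pre_r`, `post_i`, `post_s`,
#'   `post_r` plus the cohort's id/demographic columns).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_total = 5))
#' photos <- simulate_photo_layer(cohort, scale_jitter = 0.2, seed = 3)
#' all.equal(correct_photo_measurements(photos)$post_incision, cohort$post_incision)
simulate_photo_layer <- function(records, scale_jitter = 0.1, ref_length = 1,
                                 seed = 1L) {
  if (!is.numeric(scale_jitter) || length(scale_jitter) != 1L ||
    is.na(scale_jitter) || scale_jitter < 0) {
    abort_input("`scale_jitter` must be a single non-negative number")
  }
  check_positive_finite(ref_length, "ref_length")
  need <- c("corrected_width", "corrected_length", "designed_arc", "post_incision")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort_input(sprintf(
      "`records` is missing columns: %s", paste(missing_cols, collapse = ", ")
    ))
  }
  n <- nrow(records)
  withr::with_seed(as.integer(seed), {
    pre_s <- exp(rnorm(n, 0, scale_jitter))
    post_s <- exp(rnorm(n, 0, scale_jitter))
    altitude <- exp(rnorm(n, 0, scale_jitter))
  })
  pre_r <- ref_length * pre_s
  post_r <- ref_length * post_s * altitude
  keep <- setdiff(names(records), need)
  out <- tibble::as_tibble(records[keep])
  out$measured_length <- records$corrected_length * pre_s
  out$measured_width <- records$corrected_width * pre_s
  out$pre_i <- records$designed_arc * pre_s
  out$pre_s <- pre_s
  out$pre_r <- pre_r
  # invert the altitude-discrepancy correction so the round trip is exact
  out$post_i <- records$post_incision * post_s * post_r / pre_r
  out$post_s <- post_s
  out$post_r <- post_r
  out
}
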
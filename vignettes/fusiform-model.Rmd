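---
title: "The intersecting-circle model of fusiform excision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The intersecting-circle model of fusiform excision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiform)
library(dplyr)
```

## The model

A "fusiform" (often loosely called "elliptical") excision is the lens-shaped
skin island a surgeon draws around a small lesion so the wound closes in a
straight line. The shape implemented here is bounded by two arcs of
*identical* circles of radius $r$ that intersect at the two vertices $A$ and
$B$. Its two free parameters are the length $l$ (the chord $AB$, major axis)
and the width $w$ (the segment $DE$ across the middle, minor axis); each
arc's sagitta is $w/2$. All lengths are in cm, all angles are exposed in
degrees (the clinical convention), and trigonometry is done internally in
radians through a single pair of conversion helpers.

Three angles describe the vertex, and keeping them apart is the model's
main clinical point:

* the **apical inner angle** $\beta = \angle DAE$, subtended at a vertex by
  the width endpoints;
* the **apical tangent angle** $\alpha$, between the two circles' tangent
  lines at a vertex — this is what most of the surgical literature calls
  *the* apical or vertex angle;
* the **central angle** $\theta = \angle AOB$ at a circle's centre.

For equal intersecting circles these satisfy the exact identity

$$\theta = \alpha = 2\beta,$$

and the forward geometry is closed-form:

$$\beta = 2\arctan\!\frac{w}{l}, \qquad
  l = \cot\!\frac{\beta}{2}\,w, \qquad
  r = \frac{l^2 + w^2}{4w}, \qquad
  a = r\,\theta_{\mathrm{rad}}
    = \frac{\beta}{360^\circ}\,\pi\left(1 + \cot^2\!\frac{\beta}{2}\right) w,$$

where $a$ is the length of one bounding arc. The model's prediction is that
the healed incision follows the *arc*, not the chord: the final wound
length is $a$, and each designed vertex is pushed outward along the major
axis by the **push-out distance**

$$e = \frac{a - l}{2} \ge 0.$$

A convenient way to see the whole design space is through the
dimensionless ratios $a/w$, $l/w$ and $e/w$ as functions of $\beta$ on the
canonical domain $\beta \in (0^\circ, 90^\circ]$ ($l \ge w$): the first two
decrease strictly with $\beta$, $e/w$ increases, and
$a/w - l/w = 2\,e/w$ identically. At the circular limit $l = w$
($\beta = 90^\circ$) the ratio $a/w$ attains its minimum $\pi/2$.

```{r curves, fig.width = 6, fig.height = 3.5}
autoplot(design_curves(seq(5, 90, by = 0.5)))
```

Some checkpoints the package computes (and tests):
a 3:1 design has a tangent angle of $4\arctan(1/3) \approx 73.7^\circ$
(rounding to the familiar "74 degrees") and $r = 2.5\,w$, i.e. five times
the semi-minor axis; pushing the tangent angle down to the textbook
"30 degrees" requires $l/w = \cot 7.5^\circ \approx 7.6$; a 4:1 design has
a tangent angle rounding to $56^\circ$.

### Numerical choices

* **Inversion.** $a/w$ is strictly decreasing in $\beta$ on
  $(0^\circ, 90^\circ]$, so `invert_arc_width_ratio()` brackets the unique
  root and calls `uniroot()` with absolute tolerance $10^{-10}$ degrees
  (the bracket's lower end is found by halving from $45^\circ$). Ratios
  below $\pi/2$ are infeasible and rejected; inverse design is restricted
  to the canonical domain because surgical designs have $l \ge w$, while
  the forward model accepts wider-than-long lenses and merely flags them
  `canonical = FALSE`.
* **Degenerate inputs.** $w = 0$ means infinite radius: `circle_radius()`
  errors, while `fusiform_outline()` returns the doubled chord with a
  warning (useful for plotting limits). Non-positive lengths error with a
  dedicated condition class.
* **Display.** Values are displayed at 3 decimals (matching the clinical
  reporting precision) but never rounded internally; JSON reports carry
  full double precision.
* **Outlines.** `fusiform_outline()` places the centroid at the origin,
  major axis along $+x$, $y$ up, and pins the four landmarks
  $(\pm l/2, 0)$, $(0, \pm w/2)$ exactly, so the discretization error
  lives only strictly between landmarks. The SVG template is written at
  1 cm = 10 user units (1 unit = 1 mm when printed at native size).

## Photographic correction

Designed and healed incisions are measured on photographs in arbitrary
photo units. Each photo contains a ruler ("scale", read here as photo
units per cm — the orientation that makes the correction rules
dimensionally yield cm) and a reference object of fixed physical size
visible in both photos. The two correction rules are

$$\text{pre (cm)} = \frac{\text{raw}}{\text{pre}_s}, \qquad
  \text{post (cm)} =
  \frac{\text{raw}_{\text{post}} \times \text{pre}_r}
       {\text{post}_s \times \text{post}_r},$$

the second using the reference-object ratio to cancel the altitude
(camera-distance) discrepancy between the two photos; when the reference
reads the same in both it reduces to the scale-only rule. The width, like
every preoperative quantity, is corrected with the preoperative rule.
Missing or non-positive calibrators fail loudly — there is deliberately no
silent fallback to scale-only correction, because a missing reference is
exactly the situation in which the scale alone is untrustworthy.

## Cohort pipeline

`compute_model_columns()` evaluates the model on each case's corrected
length and width; `summarize_by_location()` gives mean (sample SD,
$n-1$ denominator) per body site — head, neck, abdomen, upper limbs,
lower limbs — and overall, flagging single-case groups as degenerate
rather than reporting an undefined SD; `compare_paired()` runs a
two-sided **paired** t-test plus the Pearson correlation. A paired test
(rather than two-sample) is used because both lengths are measured on the
same incision, which is also why a correlation is reported alongside.
Incomplete pairs are dropped listwise per comparison and counted. If the
paired differences are constant to floating precision the t statistic is
degenerate: the p-value is `NA` (flagged `zero_variance`) when the
constant is zero, and 0 when it is not — an exactly constant nonzero
difference is infinitely significant, and reporting either case as a
quiet finite number would be misleading.

The two comparisons of scientific interest are *designed length vs healed
incision* (expected significantly different: wounds heal longer than the
drawn chord) and *model arc vs healed incision* (expected
indistinguishable if the arc prediction is right).

## What the synthetic cohorts emulate

Because the underlying clinical measurements are not deposited anywhere,
the package ships a seeded generator whose defaults reproduce the
published structure of the 101-case validation cohort:

* site mix 66/6/11/13/5 over head/neck/abdomen/upper limbs/lower limbs;
* per-site preoperative width as a truncated normal with the published
  mean/SD per site (head 0.565 ± 0.175 cm through lower limbs
  0.702 ± 0.361 cm) — truncated normals rather than lognormals because
  only mean (SD) pairs are published, with a floor of 0.05 cm to avoid
  degenerate specs;
* a length-to-width ratio of 2.18 ± 0.39 shared across sites, truncated
  at 1.05 so every simulated design is canonical;
* the designed (hand-drawn) incision line equal to the model arc plus
  additive $N(0, 0.05\ \text{cm})$ drawing/measurement noise — 0.05 cm is
  roughly the half-millimetre precision with which a drawn line can be
  traced and measured, and is consistent with the published designed-arc
  and model-arc summaries differing only in the second decimal;
* the healed incision equal to the model arc times
  $1 + N(0, \mathrm{CV} = 0.05)$ — multiplicative rather than additive
  because incision lengths span roughly 0.6–3.6 cm and a fixed absolute
  noise would distort the small lesions;
* demographics with the published margins (age 37.0 ± 14.5 years, 57.4 %
  female).

A single integer seed fixes the whole draw (`withr::with_seed`, so the
caller's RNG stream is untouched), and the same seed yields a
byte-identical cohort CSV. `simulate_photo_layer()` additionally embeds
the true cm lengths into raw photo units with log-normal scale and
reference jitter, constructed as the exact algebraic inverse of the
correction rules, so the full read–correct–analyze path can be tested
end to end with zero round-trip error.

**What passing tests do and do not show.** The generator draws the healed
incision *from the model* plus noise; simulations can therefore verify
that the pipeline recovers a true arc-law signal at the study's sample
sizes (the arc comparison stays non-significant at close to the nominal
5 % rate across 200 seeded 101-case replicates, while the length
comparison is essentially always significant, and a $10^4$-case cohort
recovers the configured moments to Monte-Carlo precision). They cannot
re-verify the clinical claim itself — that real skin heals along the arc —
nor do they model skin elasticity, site-specific healing, dog-ear
formation, or per-site differences in the length-to-width ratio (a
config override exists but has no published default). The published
per-case data are private, so the package asserts nothing about the
observed cohort's specific means, correlation ($r = 0.917$) or p-values;
it reproduces the *pattern* those statistics exhibit under the model.

Problem sizes used throughout the test suite — 200 replicates of 101
cases, one $10^4$-case recovery cohort, $10^6$-segment discretization
oracles on 100 random designs — were chosen as the smallest scales at
which the binomial and Monte-Carlo tolerances are sharp enough to be
informative.

## Worked example

```{r example}
geom <- fusiform_geometry(3, 1)
geom |> select(inner_angle, tangent_angle, radius, arc, pushout)

cohort <- simulate_cohort(cohort_sim_config(seed = 7)) |>
  compute_model_columns()
compare_paired(cohort, corrected_length, post_incision) |> tidy()
compare_paired(cohort, model_arc, post_incision) |> tidy()
```

## Known limitations

* The model is purely geometric: closure tension, skin elasticity and
  tissue redistribution are not represented, so predictions degrade for
  large lesions or highly mobile sites.
* The inverse solvers cover only the canonical domain $l \ge w$.
* The photographic correction assumes the two printed algebraic rules;
  no perspective or stereo rectification is attempted.
* Design-noise and healed-incision noise levels are package choices
  consistent with the published summary tables, not fitted to per-case
  data (which are unavailable).
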
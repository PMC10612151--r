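# fusiform

Geometry and validation tools for **fusiform ("elliptical") skin
excision** — the lens-shaped excision used for small benign lesions with
primary closure. The package implements the equal-diameter
intersecting-circle model of that shape and everything needed to use and
validate it: forward geometry, inverse design, final-wound-length
prediction, printable incision templates, the photographic
scale/reference-object measurement correction, a cohort analysis
pipeline, and a seeded synthetic-cohort generator. It is written for
surgeons and biostatisticians who want quantitative answers to two
practical questions: *what vertex angle does a given length-to-width
ratio actually produce*, and *how long will the wound be after closure*.

## The model

The excision is bounded by two arcs of identical circles of radius *r*
meeting at the vertices. With length *l* (chord between the vertices) and
width *w* (minor axis), the apical **inner** angle β, apical **tangent**
angle α (what the literature usually calls "the vertex angle") and the
**central** angle θ obey the exact identity θ = α = 2β, and

    β = 2·arctan(w/l)        l = cot(β/2)·w        r = (l² + w²)/(4w)

    a = r·θ_rad = (β/360°)·π·(1 + cot²(β/2))·w     (one-sided arc length)

The model predicts that the healed incision follows the **arc**, not the
chord: final wound length *a*, with each designed vertex pushed outward by
e = (a − l)/2. Consequences worth knowing: a 3:1 design has a tangent
angle of ≈74°, not 30°, and its arc radius is exactly 5× the semi-minor
axis; a true 30° tangent angle needs a 7.6:1 design.

## Worked example

```r
library(fusiform)

fusiform_geometry(3, 1)
#> # A tibble: 1 × 12
#>   length width inner_angle tangent_angle central_angle radius   arc pushout
#>    <dbl> <dbl>       <dbl>         <dbl>         <dbl>  <dbl> <dbl>   <dbl>
#> 1      3     1        36.9          73.7          73.7    2.5  3.22   0.109
```

A 3 × 1 cm design: the vertex (tangent) angle is 73.7°, the generating
circles have radius 2.5 cm, the predicted final wound is 3.22 cm — 0.22 cm
longer than the drawn length, i.e. each vertex migrates outward by
0.109 cm during closure.

The cohort pipeline on a simulated 101-case study (site mix, width and
length-to-width distributions matching the published validation cohort):

```r
cohort <- simulate_cohort(cohort_sim_config(seed = 7)) |>
  compute_model_columns()

compare_paired(cohort, corrected_length, post_incision)
#> Paired comparison: corrected_length vs post_incision (n = 101)
#>   corrected_length: 1.402 (0.448)   post_incision: 1.600 (0.488)
#>   mean difference -0.199, t(100) = -19.363, p = 1.32e-35
#>   Pearson r = 0.979

compare_paired(cohort, model_arc, post_incision)
#> Paired comparison: model_arc vs post_incision (n = 101)
#>   model_arc: 1.595 (0.491)   post_incision: 1.600 (0.488)
#>   mean difference -0.005, t(100) = -0.619, p = 0.537
#>   Pearson r = 0.986
```

The healed incision is highly correlated with, but significantly *longer*
than, the designed length — while it is statistically indistinguishable
from the model arc. That is the arc-law pattern the model predicts.

Other entry points: `design_curves()` + `autoplot()` for the
dimensionless design chart, `invert_arc_width_ratio()` for inverse
design, `fusiform_outline()` / `write_fusiform_svg()` for printable
templates, `simulate_photo_layer()` + `correct_photo_measurements()` for
the photogrammetric round trip, `read_cohort()` / `render_report()` for
CSV/JSON I/O, and a thin CLI at `inst/cli/fusiform.R` with subcommands
`design`, `invert`, `curves`, `template`, `simulate`, `analyze`.

See `vignettes/fusiform-model.Rmd` for the full account of the model,
its assumptions, and what the synthetic cohorts do and do not emulate.

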
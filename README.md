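# disctrace

Agreement and precision analysis for hand-traced optic disc boundaries in
retinal fundus images.

Building ground-truth datasets for automated disc segmentation means asking
several raters to trace the same discs — and then asking how much they
agree, where they disagree, and whether cheap geometric repairs of tracing
artifacts help. `disctrace` implements that analysis end to end for studies
with two raters plus a reference ("ground truth") tracing per image,
stratified by dataset and retinal condition (glaucoma, diabetic
retinopathy, normal), and compared before vs. after ellipse-fit repair.

## What it computes

For each image and each pair of tracings (rater vs. rater, rater vs.
ground truth):

* **Region kappa** — Cohen's kappa over the pixels of a bounding box
  spanning the compared tracings: κ = (P₀ − Pₑ)/(1 − Pₑ), with P₀ the
  observed proportion of identically labelled pixels and
  Pₑ = pₐp_b + (1−pₐ)(1−p_b) the chance agreement. Restricting to the box
  keeps κ from being inflated by the vast agreeing background.
* **Border kappa** — the same statistic after reducing each mask to its
  outer contour dilated to a band (default ±2 px): region kappa saturates
  when regions overlap in bulk; this variant exposes border disagreement.
* **Dice** — 2|A∩B| / (|A|+|B|) on foreground pixels.
* **Average boundary distance (μd)** — rays are cast from the reference
  tracing's centroid in 12 directions (default 0°, 30°, …, 330°);
  μd = mean |d_k(ref) − d_k(test)| over the directions where both
  tracings intersect the ray, in pixels.
* **Ellipse-fit repair** — each rater tracing can be replaced by its
  direct least-squares ellipse (conic Ax² + Bxy + Cy² + Dx + Ey + F = 0
  constrained to B² − 4AC < 0, solved via the numerically stable block
  decomposition of the constrained eigenproblem). This absorbs
  "misaligned" stroke arcs but can flatten genuinely non-elliptic discs;
  the pipeline reports every metric with and without it.

A synthetic study generator (elliptical-ish true discs; simulated raters
with radial jitter, occasional misaligned arcs, and a glaucoma-gated
outward sector bias emulating confusion of the disc border with
peripapillary atrophy) makes the whole pipeline testable without any image
downloads. Real tracings (PNG/TIFF masks or CSV/JSON boundary polylines,
listed in a manifest) are analyzed through the same interface.

## A worked example

```r
library(disctrace)

config <- synthetic_study_config(seed = 1)   # 159 images: 69 glaucoma + 37 normal
records <- generate_study(config)            #   (Drishti-like) + 53 DR (ARIA-like)
report <- run_study(records)                 # 3 pairs x {raw, ellipse-fitted}

subset(report$by_dataset, pair == "od1-od2",
       c(dataset, fitted, kappa_region, kappa_border, region_band, border_band))
#>  dataset fitted kappa_region kappa_border    region_band    border_band
#>     aria  FALSE    0.9348678    0.7697294 almost-perfect    substantial
#>     aria   TRUE    0.9562977    0.8374567 almost-perfect almost-perfect
#>  drishti  FALSE    0.9131641    0.6764895 almost-perfect    substantial
#>  drishti   TRUE    0.9320654    0.7563203 almost-perfect    substantial

subset(report$by_condition, pair == "od1-gt" & !fitted, c(condition, dice, mu_d))
#>  condition      dice      mu_d
#>         dr 0.9912579 0.7138365
#>   glaucoma 0.9724670 2.0184179
#>     normal 0.9925080 0.6103604
```

Reading this: the two simulated raters agree almost perfectly on the disc
*region* (κ ≈ 0.91–0.93) but only substantially on the *border*
(κ ≈ 0.68–0.77) — border agreement is always the weaker statistic, and
ellipse fitting raises it by repairing misaligned strokes. Across
conditions, glaucomatous images are the least precise (highest μd, here
≈ 2.0 px vs ≈ 0.6–0.7 px elsewhere) because both simulated raters push
the border outward into the PPA region on those images, each by a
different amount. `report$per_image` holds the underlying per-image rows;
`report_markdown()`/`write_report()` render and save the tables.

A thin CLI over the same functions lives at
`inst/scripts/trace_study.R` (subcommands `simulate`, `analyze`,
`report`).

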
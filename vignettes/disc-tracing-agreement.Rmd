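---
title: "Quantifying agreement between optic disc tracings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying agreement between optic disc tracings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disctrace)
```

## The problem

Training segmentation models on fundus photographs requires reliable hand
annotations of the optic disc, but hand tracing is subjective: raters
disagree about where the disc ends, particularly in glaucomatous eyes where
peripapillary atrophy (PPA) — a degenerated ring abutting the disc — is
easily mistaken for disc tissue. Annotation tools add their own artifacts:
a stroke can derail from its intended path for part of its course (a
"misalignment"), leaving a tracing that is correct except for one displaced
arc.

`disctrace` quantifies both phenomena. Given several tracings of the same
image (two raters plus a reference "ground truth"), it measures

* how well raters agree on the disc *region* and on the disc *border*
  (bounding-box Cohen's kappa, in two variants),
* how precisely each rater matches the reference region (dice overlap),
* how precisely each rater matches the reference *boundary* (the average
  radial boundary distance), and
* whether replacing each tracing by its best-fit ellipse — a cheap repair
  for misaligned strokes — helps or hurts each of these.

Because the original fundus datasets require downloads and licenses, the
package ships a synthetic study generator that emulates the relevant
structure of such data; every claim the package makes is testable against
it. Real tracings are accepted through the same manifest interface.

## The metrics

**Region kappa.** Every pixel in a bounding box around the disc is an item
rated disc/background by each tracing, and

$$\kappa = \frac{P_o - P_e}{1 - P_e},$$

where $P_o$ is the proportion of identically labelled pixels and
$P_e = p_a p_b + (1-p_a)(1-p_b)$ is the agreement expected by chance from
the two foreground fractions. The box matters: computed over the whole
image, $\kappa$ is inflated by the vast agreeing background. The box is the
tight span of the lowest/highest x and y over the foreground of the masks
compared (`union_bounding_box()`), by default the pairwise box of exactly
the two masks in each comparison (`bbox_scope = "pair"`); a study-wide
`"all"` scope is available. When $P_e = 1$ (both tracings constant over
the box, necessarily equal) kappa is defined as 1 rather than 0/0.

**Border kappa.** Region kappa saturates once two tracings overlap in bulk,
saying nothing about the border. The border variant first reduces each mask
to its outer contour dilated by a disc of radius `border_tolerance`
(default 2 px, `boundary_band()`), then applies the same kappa. Two borders
that run parallel more than ~2 px apart produce near-disjoint bands and a
kappa near zero even when the region kappa is above 0.8 — which is exactly
the contrast this metric exists to expose.

**Dice.** $2|A \cap B| / (|A| + |B|)$ on foreground pixel counts.

**Average boundary distance ($\mu_d$).** From the centroid of the
*reference* tracing, a ray is cast at each of 12 directions; $d_{k}^{ref}$
and $d_{k}^{test}$ are the distances at which the ray leaves each tracing,
and $\mu_d$ is the mean of $|d_k^{ref} - d_k^{test}|$ over directions where
both are defined. Both distances are measured from the same centroid, so
the metric is deliberately asymmetric in its arguments. The default
direction set is uniform 30° spacing (0°, 30°, …, 330°). A commonly
printed variant of this 12-direction list replaces 30° by 20° (an
irregular spacing we believe to be a typo); it is available as
`angle_set = "printed"` for sensitivity analysis.

Kappa values are banded qualitatively (`interpret_kappa()`): below 0
less-than-chance, 0.01–0.20 poor, 0.21–0.40 fair, 0.41–0.60 moderate,
0.61–0.80 substantial, 0.81–0.99 almost perfect. The two-decimal cut-offs
are realized with half-step boundaries (0.005, 0.205, …) so every value
has a band.

## Ellipse-fit repair

Optic discs are approximately elliptical, so a misaligned tracing can be
repaired by replacing it with its best-fit ellipse. The fit is the direct
least-squares conic fit: minimize the algebraic distance of the boundary
points to the conic $Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0$ subject to the
ellipse constraint $B^2 - 4AC < 0$. We implement the numerically stable
block decomposition: with the quadratic design block $D_1$ (rows
$x^2, xy, y^2$), linear block $D_2$ (rows $x, y, 1$) and scatter blocks
$S_1 = D_1^T D_1$, $S_2 = D_1^T D_2$, $S_3 = D_2^T D_2$, the quadratic
coefficients are the eigenvector of
$M = C_1^{-1}(S_1 - S_2 S_3^{-1} S_2^T)$ satisfying $4ac - b^2 > 0$, with
constraint matrix $C_1 = [[0,0,2],[0,-1,0],[2,0,0]]$, and the linear
coefficients follow as $a_2 = -S_3^{-1} S_2^T a_1$. The test suite checks
this implementation against an independent oracle that solves the classic
one-shot 6×6 constrained generalized eigenproblem.

Numerical choices worth knowing:

* **Conditioning.** Points are translated to their centroid and scaled to
  RMS radius $\sqrt 2$ before the fit, and the conic mapped back
  afterwards. At fundus pixel scales (coordinates up to ~2,900) the raw
  scatter blocks are ill-conditioned; the transform is mathematically
  neutral and the round trip is exact to ~1e-13.
* **Eigenvector selection.** Exactly one eigenvector satisfies the ellipse
  constraint in exact arithmetic; numerically we take the one with the
  largest positive $4ac - b^2$.
* **Which points are fitted.** For polyline input, all vertices —
  misaligned arcs included, since the fit is what absorbs them. For mask
  input, the ordered outer contour of the largest 8-connected component.
* **Half-pixel compensation.** Contour pixels of a rasterized region have
  centers up to one pixel inside the continuous boundary, so a fit through
  them under-estimates the axes by about half a pixel; for mask input the
  fitted semi-axes are enlarged by 0.5 px, which makes refitting a
  rasterized ellipse a fixed point (dice ≥ 0.99). Polyline vertices are
  continuous coordinates and are not compensated.
* **Ground truth is never refit** by default: the reference is treated as
  fixed and repair is applied to rater tracings only (configurable via
  `refit_ground_truth` for sensitivity analysis).
* **Fallback.** If the fit fails (degenerate points) or the fitted conic is
  not a real ellipse, the pipeline falls back to the raw tracing and flags
  the row `fit_fallback` rather than dropping the image.

Repair is not always beneficial: when the true disc is not elliptical, the
fit flattens real boundary detail, and when a misaligned arc is large it
drags the fitted ellipse toward itself. Both directions are asserted in the
test suite (repair improves jittery misaligned tracings in aggregate;
refitting clean tracings of strongly non-elliptic discs lowers dice).

## The synthetic study generator

`generate_study()` emulates a two-rater disc tracing study:

* **Composition.** 69 glaucoma + 37 normal images on a Drishti-like grid
  and 53 diabetic-retinopathy images on an ARIA-like grid (159 total).
  The Drishti preset is 724 × 486 px — a quarter-scale stand-in for the
  source dataset's 2,896 × 1,944 px images, chosen to keep a full study
  tractable on a laptop; ARIA is 768 × 576 px at full scale. Note that
  quarter-scaling removes the resolution asymmetry that in full-resolution
  data inflates Drishti pixel distances roughly fourfold.
* **True discs.** Ellipses with semi-axes drawn uniformly from 8–14% of
  the image width, random rotation, center near the image middle. A smooth
  low-order angular perturbation (orders 2–3, amplitude 5% for glaucoma,
  3% otherwise) makes the truth non-elliptic to a realistic degree —
  glaucomatous discs slightly more so, reflecting PPA-distorted margins.
* **Observers.** Each rater traces the boundary in polar form about the
  true center at 1° steps: Gaussian radial jitter, then condition-gated
  sector bias, then (with probability 0.15 per image) one contiguous 60°
  arc displaced by 8 px — the misalignment artifact — then circular
  moving-average smoothing (window 5) because hand strokes are smooth at
  1° resolution. The defaults give rater `od1` jitter 1.5 px and `od2`
  2.5 px, so the first rater is systematically more precise; tests rely on
  this asymmetry to catch rater-order bugs.
* **PPA bias.** For glaucomatous images only, both raters push the border
  outward in the superior and inferior sectors (od1: +5 px over 60–120°
  and 240–300°; od2: +8 px over 70–130° and 250–310°). The sectors and
  magnitudes differ between raters, so the bias lowers rater-vs-rater
  border agreement as well as rater-vs-truth precision — making glaucoma
  the least concordant condition, the central stratification contrast.

What the generator does **not** emulate: photometric content (no vessels,
no illumination gradients — raters see geometry only), freehand scribbles
or islands disconnected from the disc, rater fatigue or learning over the
study, and the fourfold resolution gap noted above. Passing tests therefore
demonstrate the pipeline's correctness and the stated qualitative
directions under a controlled observer model, not quantitative agreement
levels of any particular human study.

## Pipeline conventions

* Coordinates are 0-based, x = column, y = row increasing downward; angles
  are degrees counter-clockwise as displayed (90° = up). All distances are
  pixels of the native grid; no physical calibration is attempted.
* Rasterization of a closed polyline fills pixel centers under the nonzero
  winding rule and additionally sets pixels whose center lies on the path
  (within an eighth of a pixel): inclusive of the traced border without
  inflating area. Pixel rounding everywhere is half-up (`floor(x + 0.5)`),
  not banker's rounding, so integer translations shift rasters exactly.
* Ray casting samples every 0.25 px and returns the *farthest* foreground
  pixel on the ray: deterministic for filled masks, insensitive to
  interior holes, and for a tracing with a detached misaligned arc the arc
  wins, which is the behavior that makes $\mu_d$ sensitive to the artifact.
* For the rater-vs-rater pair, $\mu_d$ needs a reference; the pipeline uses
  the first rater's tracing as reference and records
  `mu_d_reference=od1` in the row flags rather than leaving the cell
  blank.
* Aggregation is per-image-then-mean (unweighted) within each
  (pair, dataset, fitted) and (pair, condition, fitted) stratum, matching
  distribution-style summaries of per-image values; pooling pixels across
  images is deliberately not offered, as it would weight large discs more.

## Problem sizes

The test suite simulates 50-image studies for the direction-of-effect
checks (misalignment repair, non-elliptic harm) and three full 159-image
studies (seeds 1–3) for the condition contrast; a full study analyzed in
both fitting states takes well under a minute on one core. The
Monte-Carlo check of the observer noise model uses 500 repeated tracings
of one disc.

## A worked example

```{r example, eval = FALSE}
library(disctrace)

config <- synthetic_study_config(seed = 1)
records <- generate_study(config)      # 159 image records
report <- run_study(records)           # 3 pairs x 2 fitting states

subset(report$by_dataset, pair == "od1-od2",
       c(dataset, fitted, kappa_region, kappa_border, region_band))
subset(report$by_condition, pair == "od1-gt" & !fitted,
       c(condition, dice, mu_d))
cat(report_markdown(report))
```

## Known limitations

* Border kappa is a reconstruction: reducing each tracing to a dilated
  contour band before applying kappa is one reasonable operationalization
  of "border agreement", and its absolute values depend on the tolerance
  (default 2 px).
* The radial metric assumes tracings are star-shaped about the reference
  centroid; grossly non-star-shaped tracings yield undefined angles, which
  are excluded and flagged (error if all angles are undefined).
* Plain least squares is sensitive to large misaligned arcs by design; no
  robust/RANSAC variant is provided.
* Only two raters plus a reference are aggregated; multi-rater kappa
  generalizations are out of scope.
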
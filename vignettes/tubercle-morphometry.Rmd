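---
title: "Tubercle morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tubercle morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubermorph)
```

`tubermorph` measures the size and shape of seed-coat tubercles — the
cell-level protrusions on *Silene* (Caryophyllaceae) seeds — from calibrated
optical images, and compares those measurements across species, seed types
(rugose vs. echinate) and subgenera (*Behenantha* vs. *Silene*). This
vignette explains the procedure, its assumptions, the parameters that
matter, and the design decisions behind them.

## The measurement model

Each tubercle is reduced to a vertically oriented planar profile — a
single-valued curve $y(x)$ in microns, sitting on a base line — and
summarized by six variables:

* **W**, width at the base: the distance between the two base points along
  the base chord.
* **H**, height: the maximum perpendicular distance from the base chord to
  the profile. Whether height should be measured perpendicular to the chord
  or along the image vertical cannot be distinguished at the reporting
  precision of upright tubercles; the chord-perpendicular definition is used
  because it is rotation-invariant, and the two coincide for level bases.
* **S**, the slope index $S = 200\,H/W$ — the percent flank slope of the
  symmetric triangle with the same base and height. A tubercle twice as wide
  as it is tall has $S = 100$, which in practice separates rounded
  (rugose-type) from acute (echinate-type) tubercles.
* **maximum and mean absolute curvature** of a smooth curve fitted to the
  profile, in $\mu\mathrm{m}^{-1} \times 1000$: a curvature of 20
  corresponds to an osculating circle of radius 50 µm, a curvature of 100
  to radius 10 µm.
* their **ratio** (max/mean), a dimensionless peakedness index, $\approx 1$
  for arc-of-circle profiles and $\gg 1$ for spiky ones. As computed here —
  the maximum and the mean of the *same* sample of $|\kappa|$ — the ratio
  cannot fall below 1. Published reference tables occasionally print ratios
  below 1 (or ratios inconsistent with their own numerator and
  denominator); the package reproduces the consistent cells and documents
  the inconsistent ones in its tests rather than emulating them.

## Curve fitting

Digitized outlines carry pixel-scale noise, so curvature is never taken on
the raw points. A polynomial Bézier curve of degree $n$,
$C(t) = \sum_j \binom{n}{j} t^j (1-t)^{n-j} P_j$, is fitted by linear least
squares in the Bernstein basis with the first and last control points
pinned to the first and last data points. Curvature then comes from the
hodographs:

$$\kappa(t) = \frac{x'(t)\,y''(t) - y'(t)\,x''(t)}
                   {\left(x'(t)^2 + y'(t)^2\right)^{3/2}}.$$

Design choices, each with its rationale:

* **Degree, default 5.** High enough to represent a single bump with an
  asymmetric apex, low enough not to chase pixel noise. `degree = "auto"`
  raises the degree (to at most 10) until the residual RMS falls below
  0.5 µm — about one pixel at typical stereomicroscope scales — which is
  useful for compound bumps carrying secondary excrescences.
* **Parameterization.** Chord-length parameter values (not uniform), the
  standard for digitized outlines: uniform parameters distort curvature
  wherever point spacing is uneven. The chord-length values initialize a
  damped Gauss–Newton *parameter correction* (each point is re-projected
  onto the current curve and the curve refitted). Correction iterates are
  accepted only while the residual RMS at least halves per iteration: on
  data the degree can represent exactly, this converges geometrically to
  machine precision (so exactly representable curves are recovered); on
  data it cannot represent (noise, a near-corner), slow parameter drift
  would progressively unconstrain the end spans of the curve and let them
  whip — there the initial chord-length fit stands.
* **Endpoint handling.** The endpoint constraint makes the fitted curve
  honor the measured base points, but it also transmits noise at the two
  end pixels directly into the curve, inflating curvature near $t = 0, 1$.
  For that reason `analyze_tubercle()` applies a light 3-point moving
  average to the profile before fitting (`smooth_window = 0` disables it).
  The smoothing is deliberately weaker than the fit itself and affects W/H
  not at all (they are measured on the raw profile).
* **Cusp handling.** Where the first derivative effectively vanishes
  (below $10^{-9}$ of the control-polygon chord length) curvature is
  undefined; such samples become `NA` with a warning and are excluded from
  the summaries — never silently zeroed.

The curvature profile is sampled at $n = 200$ uniform parameter values
(matching the abscissa of the usual curvature-trace plots); the mean of
$|\kappa|$ is the arithmetic mean over those samples. An arc-length-weighted
mean is available behind a flag (`mean_abs_curvature(weighted = TRUE)`)
because the uniform-in-$t$ choice, while conventional, is not the only
defensible averaging domain; for near-arc profiles the two agree to ~1%.

## Image extraction

The extraction path emulates a thresholding protocol: images are converted
to 8-bit grayscale, binarized (fixed level or Otsu), connected components
traced (largest first), and for each pixel column crossed by the boundary
the topmost boundary pixel is taken — a single-valued "line graph" profile.
Overhanging tubercles therefore lose their overhang (a message is emitted).
Scale comes from an in-image ruler of known physical length
(`calibrate_scale()`); ruler detection is deliberately manual — the pixel
length is an input, not an inference. Image I/O, Otsu thresholding and
boundary tracing are delegated to EBImage; the line-graph emulation,
calibration and base-line segmentation are package code.

## Statistics

Species are summarized by mean, coefficient of variation, minimum and
maximum per variable. The CV uses the sample ($n-1$) standard deviation —
the flavor that reproduces the published reference summaries exactly.
Group comparison is classical fixed-effects one-way ANOVA computed from
sums of squares (a Welch-style correction is intentionally absent from the
default, matching the common point-and-click default), followed by Tukey
HSD on the studentized range with the Tukey–Kramer standard error for
unbalanced designs, and a compact letter display via the insert-and-absorb
algorithm. Letters are issued in increasing order of group mean (smallest
mean = "a", ties broken alphabetically); the published tables do not state
their letter orientation, so ours is fixed and documented here.

Pooled group rows (seed type, subgenus) can be computed two ways — from raw
records, or as tubercle-count-weighted means of per-species summaries — and
the two agree to numerical precision whenever the species means do. The
packaged reference tables contain two pooled cells (the rugose group's
curvature means) that cannot be derived from their own per-species rows by
any weighting; the tests document this rather than hiding it.

## Clustering

Species are clustered on their trait-mean vectors (default: all six
variables; a single-variable matrix such as maximum curvature only is
equally supported) with Euclidean distances under Ward's minimum-variance
criterion in the `ward.D2` formulation — squared distances inside the
Lance–Williams update, merge heights on the distance scale — the common
default of major statistical packages. No standardization is applied by
default (none is mentioned for the published dendrogram), but a z-score
flag exists because the six variables have heterogeneous scales and the
slope index otherwise dominates the distances. Newick export writes branch
lengths as merge-height differences, so the tree is ultrametric with leaf
depth equal to the final merge height.

On the packaged 31-species reference means, the two-cluster Ward cut
isolates a cluster consisting entirely of subg. *Behenantha* species — the
high-curvature, high-slope echinate extreme — while the remaining
*Behenantha* species (four of which have rugose seeds with rugose-typical
trait values) stay with the subg. *Silene* majority. Subgenus and seed type
are correlated but not congruent, and the dendrogram reflects the traits,
not the taxonomy.

## The synthetic generator

Because no raw per-tubercle dataset is distributed, every stage is
validated against a seeded synthetic generator (`bump_spec()`,
`make_profile()`, `make_species_dataset()`, `render_profile_image()`). It
emulates:

* **rounded** (rugose-type) bumps as raised cosines, default
  $W = 83.3$, $H = 20.7$ µm — the pooled rugose class means;
* **acute** (echinate-type) bumps as triangles with the apex blended by a
  parabola of corner radius $W/20$ (flank slope solved so the bump peaks at
  exactly $H$ with its base at $y = 0$), default $W = 72.0$, $H = 43.6$ µm;
* **compound** bumps — a rounded bump plus a smaller off-center secondary
  excrescence;
* **arc** — a circular arc of given radius, the constant-curvature control
  shape used to pin the unit convention ($\kappa \times 1000 = 1000/r$).

Per-tubercle $(W, H)$ draws are log-normal (positivity; CVs default to the
pooled class values, ~23–50%); measurement noise is additive Gaussian on
$y$ with default sd 0.5 µm, about one pixel at the reference image scale;
profiles default to 100 points, about the column count of a typical
tubercle crop. All randomness flows from explicit seeds, and the generator
restores the global RNG state.

What the generator does and does not establish: it reproduces the class
geometry ($W$, $H$, and hence $S$) faithfully, so tests of extraction,
measurement and group statistics on those variables carry over to real
images. Its curvature summaries, however, are consequences of the chosen
shape families, not calibrated to the published class values: a raised
cosine at the rugose class means has an apex curvature near 59 (×1000/µm)
where real rugose tubercles average ~41, and the straight flanks of the
triangular echinate emulation pull its *mean* curvature down to roughly the
rounded class's level, so the published rugose-vs-echinate mean-curvature
contrast is *not* reproduced by the default generator (its sign usually is,
its significance is not). Tests of curvature therefore rely on shapes with
known ground truth (arcs, exact polynomials, finite-difference oracles)
rather than on class realism, and passing them says nothing about whether
real rugose and echinate populations differ — that is the published data's
claim, not the generator's.

## Numerical and degenerate-input policy

* Consecutive duplicate points are rejected before fitting (chord-length
  parameters would collapse).
* Collinear input is accepted; the fit is exact and curvature is 0; the
  max/mean ratio of an all-zero curvature profile is flagged `NaN`.
* Tie-breaks in clustering follow `stats::hclust`'s deterministic merge
  order; identical rows merge at height 0.
* Report rounding follows the reference tables: W, H to integers; S,
  curvatures and ratio to one decimal (`round_records()`).
* Pipeline CSV outputs are written at fixed precision so identical runs are
  byte-identical.

## Problem sizes used in the tests

The suite validates the geometry on 60-point arcs and ≤ 120-point bumps
(degrees 2–10), the statistics on the packaged 66-row reference table plus
simulated two-class datasets of 50 tubercles per class, type-I error on
1000 null replicates, the image round trip on 20 rendered bumps at 0.5
µm/px, and the Ward oracle on matrices of up to 8 rows — sizes chosen so
the whole suite runs in well under a minute while still exercising every
code path at the scales the method is used at.

## Known limitations

* Overhanging (mushroom-shaped) tubercles are reduced to their top surface
  by the line-graph extraction; their W is measured at the crop bounds, not
  the true neck.
* The endpoint-constrained fit trusts the two base points; a badly chosen
  base crop biases curvature near the ends even after smoothing.
* Curvature summaries depend on the fitted degree for non-smooth shapes
  (a degree-5 fit of a near-triangular bump places its curvature maximum
  at the base corners; `degree = "auto"` resolves the apex).
* The synthetic classes are geometric idealizations; see above for what
  they do not emulate.
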
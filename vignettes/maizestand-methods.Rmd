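---
title: "Stand detection and plant spacing from plot-scale UAV imagery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand detection and plant spacing from plot-scale UAV imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizestand)
```

This vignette documents the models, parameter choices and numerical
conventions behind `maizestand`, and what its simulator-based validation
does and does not demonstrate.

## Imaging model

A nadir pinhole camera at flight height $H$ with diagonal field of view
$\theta_d$ and a $w \times h$-pixel sensor resolves the ground at

$$\mathrm{GSD} = \frac{2H\tan(\theta_d/2)}{\sqrt{w^2+h^2}}$$

metres per pixel. The field of view is interpreted as *diagonal* — the
convention of consumer-drone spec sheets, which quote one angle for a 4:3
sensor — and the GSD is taken over the pixel diagonal accordingly. We
assume flat terrain, an exactly nadir optical axis, and negligible lens
distortion within a single plot-scale frame; multi-image mosaicking,
gimbal-tilt and rolling-shutter effects are out of scope. The ground frame
origin sits at the image centre (the nadir point), with 0-based pixel
indices and pixel centres at integer coordinates.

A canopy at height $h$ above the soil appears displaced radially *away*
from nadir. With a single global canopy height (`plant_height`, default
0.10 m — an average measured over a second-leaf-collar stand), the apparent
ground position $\mathbf{p}$ of a plant maps back to its field position as
$\mathbf{p}\,(H-h)/H$. The correction is applied at the canopy top
($h$ itself); a `height_fraction` knob (default 1.0) exposes the mid-canopy
alternative ($h/2$) for users who consider the centroid of the visible
canopy to sit lower. The forward model used by the simulator is the exact
inverse, $\mathbf{p}\,H/(H-h)$, and both are tested as an inverse pair to
$10^{-9}$ m.

One caveat worth stating: published spatial resolutions for this camera
class at 4–5 m (1.1–1.4 mm) are slightly finer than the diagonal pinhole
reading of a 78.8° FOV gives (≈1.31–1.64 mm). No documented reading of the
single quoted angle reproduces them, so the formula above is the contract
and printed vendor resolutions are treated as approximations.

## Segmentation

Vegetation is separated from soil by the excess-green index
$\mathrm{ExG} = (2g-r-b)/(r+g+b)$ on normalized bands, thresholded at 0.1.
Numerical conventions the literature leaves open are fixed as follows:

* **Normalization** divides each band by the bit-depth maximum (255 for
  8-bit) rather than the per-band image maximum. With equal normalizers the
  ratio is identical on raw digital numbers, and the result does not change
  when a scene is cropped; per-image band maxima are available as a config
  option (`normalization = "per_band_image_max"`).
* The threshold comparison is **strict** (`ExG > 0.1`); pixels exactly at
  the threshold are background. Pixels with zero band sum map to ExG 0.
* Objects are connected components under **8-connectivity** by default —
  leaf tips are thin, often diagonal structures — with 4-connectivity as an
  option. Labeling is a run-based union-find; the test suite cross-checks
  its 4-connected mode against an independent implementation (EBImage).
* **Perimeter** is the count of member pixels with at least one 4-neighbour
  outside the component: simple, integer-valued, and consistent across
  connectivity choices.

Two *relative* filters then remove residue and weed outliers: with
$\bar A$ and $\bar S$ the mean area and mean perimeter/area ratio over all
objects in the image, objects with $A < 0.3\,\bar A$ are removed, as are
objects failing the shape criterion. Both criteria are evaluated against
the *pre-filter* means in a single pass. The direction of the shape
criterion is genuinely ambiguous in the source literature: read literally,
"ratio less than $0.3\,\bar S$" removes *compact* objects, while the stated
goal (removing small outliers) suggests removing *thin* ones
(high ratio). Both are implemented
(`shape_filter_mode = "literal_less_than"` is the default, `"thin_object"`
the alternative); no intent is guessed beyond the switch.

Fragments of one plant — leaves split off by shade or mixed-pixel gaps —
are merged by dilating the filtered mask with a square element and merging
objects whose dilated footprints become connected. The element is
$10\times10$ px by default, suited to ~1.3 mm GSD; at other resolutions it
should scale so the ground reach stays at a few centimetres (the package's
own reduced-resolution validation uses 5 px at 6.6 mm GSD, a ~3 cm reach).
A $10\times10$ element has no centre pixel; it is anchored to cover offsets
$-4..+5$ in each axis. Because merging uses *connectivity* of the dilated
mask rather than strict overlap, the result is insensitive to this anchor
convention. Merged statistics are recomputed from the union of the original
pixels only.

## Row fitting and spacing

Rows are recovered by iterative buffer averaging, which assumes straight,
parallel rows at a known angle (90° here, i.e. parallel to the image
vertical): take an unassigned seed centroid, draw the line through it at
the row angle, collect unassigned centroids within $w/2$ of the line
($w$ = 0.508 m row spacing), move the line to the collected centroids' mean
position, and finalise membership against the *moved* line; repeat until
all centroids are assigned.

Three open details are fixed as design choices:

* **One averaging move per row** (`refine_iters = 1`): the procedure is
  described as a single relocation, not iteration to convergence; more
  iterations are available by config.
* **Membership is re-collected against the final line** before assignment.
  The alternative (keeping the initial collection) lets a seed near the
  row edge steal neighbours from the adjacent row; re-collection makes the
  outcome depend on the line actually reported. Because the mean of points
  within $\pm w/2$ of a line lies within $\pm w/2$ itself, the re-collected
  set always contains the seed and the loop terminates.
* **Seed selection** defaults to the lowest unassigned id
  (`seed_policy = "lowest_id"`) for full determinism; `"random"` with a
  seed reproduces the randomized variant. On stands whose true rows are
  separated laterally by more than $w$, the resulting *partition* is
  invariant to the seed order (tested on simulated scenes).
* A single $w$ is used everywhere, including across a planter wheel gap
  (0.6096 m): the buffer half-width $w/2$ = 0.254 m is still far below the
  wheel-gap half-distance, so no cross-assignment occurs.

Member centroids are projected perpendicularly onto their row line; sorted
projections yield adjacent-pair distances. Projection removes the lateral
(cross-row) component, so spacing is a purely along-row quantity. Rows are
infinite lines — plot cropping is assumed upstream.

## Evaluation metrics

Detections are matched to truth one-to-one by greedy nearest-first pairing
among all pairs within a tolerance (default 0.05 m — about half the
smallest spacing observed in dense stands, so a double cannot match its
neighbour's position). Greedy matching is transparent and order-free; on
stand-like geometry (minimum 9 cm true separation, centimetre-level
detection noise) it coincides with brute-force optimal assignment, a
property the test suite verifies on 1000 random small instances.
Precision, recall, the spacing agreement index
$d_e = \tfrac1n\sum_i |d_{ie}-d_{im}|$, and relative error follow. Two
readings of "relative error" are both reported, since the aggregate
definition is ambiguous: $r = d_e/\overline{d_m}$ and the per-pair
distribution $|d_{ie}-d_{im}|/d_{im}$. An interval is *valid* only if both
endpoints are matched truth plants adjacent within their truth row: spans
across a missed plant, and intervals touching false positives, are
excluded, as is standard for this metric.

Plot-level statistics use the agronomic plot area
(length × rows × row spacing = 5 × 6 × 0.508 = 15.24 m²), the sample
(n−1) standard deviation, and half-up rounding for integer-percent
display. Group comparisons are routine one-way ANOVA and ordinary least
squares via `stats::aov`/`stats::lm` (post-hoc mean separation is out of
scope).

## The scene simulator

The simulator provides the ground truth a field campaign rarely has. Its
defaults emulate the target field conditions: 5 m × 6-row plots, 0.508 m
row spacing (optional 0.6096 m wheel gap), 9.8 plants m⁻² target
population (mean seed interval $1/(9.8 \times 0.508) = 0.201$ m), 0.10 m
plants, flights at 4–5 m. Stochastic stand defects use truncated-Normal
spacing noise (sd 0.05 m, truncated at 0.05 m) with missing probability
0.03 and double probability 0.01 (doubles offset 5–12 cm). Field reports
give observed spacing ranges (roughly 9–72 cm) rather than defect rates,
so these defaults are chosen to reproduce that range's character and are
config-exposed, not measured values. Weeds default to 0.5 m⁻², residue
streaks to 1 m⁻².

Rendering choices worth knowing:

* Plants are drawn at their **apparent** (forward-parallax) positions, so
  the centroid correction is genuinely exercised end to end.
* Each plant is a **balanced whorl** of 2–6 elliptical leaves (major axis
  3–6 cm) overlapping at the stem, with leaf length anti-correlated with
  leaf count so total projected area is roughly constant (±30%) across
  plants. Both features are deliberate: young maize stands are even-sized,
  the object centroid should coincide with the seed point (the method's
  core premise), and a relative area filter is only meaningful when true
  plants do not span a 10-fold area range.
* Soil is brown multiscale noise whose ExG stays below zero by
  construction; residue streaks are near-grey with slight red excess
  (ExG ≤ 0), with a `residue_greenish` switch that pushes some residue
  above the ExG threshold to stress the filters; weeds are small green
  blobs on and off the rows. An optional global illumination gradient
  (off by default) emulates sun/cloud variation.
* Scenes are bit-identical given the same plan, camera and seed: planning
  and rendering use private seeded RNG streams (offset by a constant) and
  restore the caller's RNG state.

What the simulator does **not** emulate — and hence what passing tests do
not show about real imagery: perspective distortion of leaves, specular
and shadow effects, plant-to-plant height variation from uneven emergence
(heights are uniform, so the parallax correction is exact by construction;
in the field, emergence spread is a known error source), overlapping
canopies at later stages, in-row weeds with maize-like spectra, and sensor
artefacts (blur, vignetting, rolling shutter). Detection scores on
synthetic scenes are therefore an upper bound for field performance; the
bundled nine-plot count table gives field-realistic accuracy levels.

## Validation problem sizes

The package validates itself on a portrait 600 × 800-px camera at 4 m
(GSD ≈ 6.6 mm) whose footprint holds a full plot — chosen because the full
5 m plot length must fit along the image's long axis, and because scenes at
this scale render in well under a second, which lets the suite run 50 noisy
and 100 noise-free end-to-end scenes. At this resolution the dilation
element is 5 px (~3.3 cm ground reach), mirroring the resolution-scaling
rule above. Noise-free scenes must yield perfect precision and recall with
every spacing within 2 × GSD of truth; noisy scenes (criterion-level
defaults above) achieve pooled precision ≈ 0.99 and recall ≈ 0.98, median
per-pair relative spacing error ≈ 0.5%, and estimated-vs-true spacing
R² ≈ 0.99. Residual misses in noisy scenes are dominated by genuinely
overlapping close pairs (doubles at ≤ 12 cm merge into one object) — the
same failure mode reported for the field method.

## Known limitations

* A single global plant height: uneven emergence biases corrected
  centroids; per-plant heights (e.g. from LIDAR) are not supported.
* Fixed global ExG threshold: no local/adaptive thresholding, so strong
  illumination gradients degrade segmentation (simulator option
  `illumination = TRUE` lets you quantify this).
* Straight parallel rows at a known angle; no automatic row-angle
  estimation, curved rows, or Hough/vanishing-point detection.
* Greedy matching is not optimal on adversarial geometries (it is on
  stand-like ones; see above).
* The CLI and file formats cover PNG + CSV/JSON; georeferenced formats are
  not handled.
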
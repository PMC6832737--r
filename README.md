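# maizestand

Early-season maize stands are rarely as uniform as the planter intended:
missing plants, doubles and uneven spacing all shift the plant-to-plant
distance distribution, and spacing variability is a long-debated candidate
driver of yield loss. `maizestand` detects individual maize plants in
plot-scale, low-altitude (4–5 m) nadir RGB imagery and estimates within-row
plant-to-plant distances, so that stand density and spacing uniformity can
be quantified without tape measures. It is aimed at agronomists and
phenotyping researchers working with small-UAV imagery of row crops at
around the second leaf collar stage (~1–7 mm ground sample distance).

## Method

The pipeline has four stages:

1. **Segmentation.** The excess-green index is computed per pixel,
   ExG = (2g − r − b)/(r + g + b) with r, g, b the normalized band values,
   and thresholded at 0.1 (vegetation iff ExG > 0.1). Connected components
   become candidate plant objects. Two *relative* filters remove outliers
   (residue, weeds): objects with area A < 0.3·Ā or failing the analogous
   perimeter-to-area shape criterion are dropped, with Ā the mean over all
   objects in the image. Fragments of a single plant (leaves split by shade)
   are re-joined by dilating the surviving mask with a square structuring
   element (10 × 10 px at ~1.3 mm GSD) and merging objects whose dilated
   footprints connect; statistics are recomputed from the original pixels.
2. **Parallax correction.** An object of canopy height h imaged from flight
   height H appears displaced radially away from the nadir point. Each
   centroid, mapped to ground coordinates via the ground sample distance
   GSD = 2·H·tan(θ_d/2)/√(w² + h²) (diagonal field of view θ_d, sensor
   w × h px), is pulled back toward nadir by the factor (H − h)/H.
3. **Row fitting and spacing.** Rows are found iteratively: a seed centroid
   defines a line at the known row angle (90°), all unassigned centroids
   within w/2 of the line (w = row spacing, 50.8 cm) are collected, the line
   is moved to their mean position, and membership is finalised against the
   moved line; this repeats until every centroid has a row. Member centroids
   are projected perpendicularly onto their row line and adjacent
   differences of the projections are the spacing estimates.
4. **Evaluation.** Against a ground-truth table, detections are matched
   one-to-one (greedy nearest-first within 5 cm) giving TP/FP/FN, precision
   TP/(TP+FP) and recall TP/(TP+FN). Spacing accuracy is the agreement
   index d_e = Σ|d_ie − d_im|/n over valid intervals — intervals touching a
   false positive or spanning a missed plant are excluded — with relative
   error r = d_e / mean(d_im) and the per-pair error distribution.

Because field campaigns rarely come with exhaustively measured truth, the
package also ships a **synthetic scene simulator**: 5 m × 6-row plots at
50.8 cm row spacing and 9.8 plants m⁻² with configurable spacing noise,
missing/double rates, weeds and crop residue, rendered at the exact forward
parallax model the correction inverts. Every simulated plant position is
known, so the whole pipeline can be validated end to end.

## Worked example

```r
library(maizestand)
cam <- camera_model(flight_height = 4, fov_diagonal = 78.8,
                    image_width = 600, image_height = 800)
sc  <- simulate_scene(scene_plan(rng_seed = 42), cam)
fit <- maize_stand(sc, seg = segmentation_params(dilation_size = 5))
fit
#> Maize stand analysis
#>   plants detected : 144 (6 rows)
#>   stand density   : 9.45 plants/m2 (15.24 m2 plot)
#>   spacing         : mean 0.206 m, sd 0.056 m (135 intervals)
#>   vs ground truth :
#>     Detection: TP 144 FP 0 FN 3 | precision 100.0%, recall 98.0%
#> Spacing agreement over 135 valid pairs:
#>   d_e 0.0015 m, r 0.007, median per-pair relative error 0.005
```

The simulated plot carries 147 true plants (3 of them doubles); the
pipeline recovers 144 — the three misses are close pairs merged into one
object — with no false detections. The mean absolute spacing error (d_e) is
1.5 mm on a 20.6 cm mean interval, i.e. valid intervals are estimated to
well under a ground-sample distance on average. `residuals(fit)` returns
the signed per-interval errors, `summary(fit)` a one-row plot summary, and
`plot(fit, image = sc)` overlays centroids and fitted row lines on the
image. On real imagery, pass the PNG path and your flight's `camera_model`
instead of a simulated scene, and supply `truth =` only if you have
surveyed positions.

Plot-level statistics for multi-plot comparisons are in
`summarize_plot()`, `one_way_anova()` and `simple_regression()`;
`example_plot_counts()` bundles a nine-plot field campaign's detection
counts across three yield-stability zones for use without imagery.

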
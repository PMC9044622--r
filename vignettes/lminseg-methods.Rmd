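---
title: "Histogram-valley thresholding and leukocyte segmentation: methods and design notes"
author: "lminseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-valley thresholding and leukocyte segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lminseg)
```

## The model and its assumptions

`lminseg` segments a single white blood cell (WBC) in a blood-smear
micrograph into nucleus, cytoplasm and background. The method is purely
intensity-based and rests on three assumptions about stained smears:

1. the nucleus is the darkest structure in the image, forming the first
   mode of the intensity histogram;
2. a valley separates that mode from the rest of the image (cytoplasm,
   red cells, plasma);
3. there is one WBC of interest, and a pixel of its nucleus identifies it.

When assumption 2 fails (constant or unimodal images) the pipeline
degrades gracefully: the threshold falls back to the initial value and the
result is flagged (`branch = "fallback"`).

### Nucleus threshold

For an image `A` normalized to [0, 1], the initial value is
`T_nc0 = Max(A)/n1 + Min(A)/n2`. The defaults `n1 = n2 = 3` put `T_nc0`
near 1/3 whenever the minimum is near black, which is where the
nucleus–cytoplasm valley of stained smears lies; both divisors are
exposed for images with a different intensity layout.

The histogram (256 bins; 8-bit sources) is cut to its first half, the
leading run of empty bins is dropped, and the counts are smoothed with a
Savitzky–Golay filter. A cubic interpolating spline through the smoothed
values is sampled at 10 points per knot, and the first strict local
maximum `x_c` followed by the first strict local minimum `x_{c+1}` are
taken in increasing intensity. If no pair exists in the current segment,
the segment grows by 10% of the bin count and the search repeats until
the histogram is exhausted.

The threshold is then assembled from `T_nc0`, `x_{c+1}` and the margin
parameter `Er` (unitless intensity, default 0.07): the midpoint of the two
values when they agree to within `Er`, and the midpoint shifted by `Er/2`
toward the other value when they disagree, the direction depending on
which is larger. The rule keeps `ε_t` inside
`[min(T_nc0, x_{c+1}) − Er/2, max(T_nc0, x_{c+1}) + Er/2]` in every
branch. `Er` controls how strongly the valley location can pull the
threshold away from the initial value; 0.07 works across the fixture
regimes and is the default the whole test suite runs under.

Three decisions here were genuinely open and are resolved as follows:

* **Equality at the branch boundary.** The printed conditions leave
  `|T_nc0 − x_{c+1}| = Er` undefined. We assign it to the midpoint
  branch; all three formulas coincide at the boundary, so the choice has
  no numerical effect.
* **Failure of the precedence condition `x_c < T_nc0`.** Later
  peak/valley pairs in the same segment are tried in order, then extended
  segments; only when everything is exhausted does the method fall back
  to `ε_t = T_nc0`.
* **Near-zero leading plateaus.** A segment whose counts occupy a single
  bin is treated as structureless rather than smoothed, because filtering
  a delta spike manufactures ripple extrema.

On smoothed data the dense-spline extrema agree with a discrete
neighbor-comparison scan to within one knot spacing; on raw, rough
sequences cubic interpolation can overshoot at flat-to-steep junctions,
which is why the flat-tail trim precedes the spline and why noise-level
wiggles may be reported as the "first" minimum. The branch rule is
designed to absorb exactly this: the reported minimum only ever moves the
threshold by a bounded amount around `T_nc0`.

### Whole cell and cytoplasm

The `n` whole-cell thresholds are `(Max(A) + T_nc0)/2 + er_i`, where the
step values `er_i` divide `[Min(A), Max(A)/3]` into `n − 1` equal pieces,
endpoints included. Two printed conventions for the step size conflict
(`Δh = (a_u − a_l)/n` versus endpoints `er_0 = a_l`, `er_{n−1} = a_u`);
we adopt the endpoint-inclusive one, `Δh = (a_u − a_l)/(n − 1)`, which
reproduces the ordering `a_l = er_0 < … < er_{n−1} = a_u`. The family
object records both the formula-exact thresholds (which can exceed
`Max(A)` when `T_nc0 > Max(A)/3`) and their values clipped to `Max(A)`;
clipping is applied when thresholding images, where a threshold above the
maximum would only inflate the average, and the exact values keep the
strict-ordering and spacing identities testable. `n = 10` by default;
the averaging is insensitive to `n` beyond a handful of steps.

Averaging the floor images compresses the cell interior to a single value
(every pixel below all thresholds maps to the mean threshold) while the
background stays bright. That compression also narrows the gap between
cell, red cells and background noise, so after Otsu binarization of the
dark class a small morphological opening (disc of radius 2) severs
noise fringes before small-object removal and hole filling; without it,
background pixels one noise standard deviation below their mean attach to
the cell rim. The Otsu threshold itself is computed in-package over the
256-bin histogram with a smallest-index tie-break — empty valley bins
produce plateaus of equally optimal thresholds, and a fixed tie rule keeps
results deterministic.

The seed pixel is the floor centroid of the largest nucleus component,
snapped to the nearest nucleus pixel for concave (lobed) shapes; seed
coordinates follow a 0-based `(row, col)` convention everywhere. The
cytoplasm is the cell minus the nucleus, with nucleus pixels outside the
cell clipped under a warning rather than silently invented.

### Touching red cells

Two fallbacks handle red cells fused to the WBC:

* **Marker-controlled watershed.** Otsu foreground → Euclidean distance
  transform → markers at local maxima separated by at least half the
  distance-map maximum (the count is chosen automatically). Markers grow
  over the inverted distance map. Before retention, adjacent basins are
  merged when their shared boundary crosses foreground at least a quarter
  of the distance-map maximum thick: watershed lines through the body of a
  lobed cell are shape artifacts, whereas true detachment necks between a
  cell and a touching red cell are only as thick as the red-cell rim.
  The merge fraction is insensitive over 0.2–0.3 on the touching fixtures;
  0.25 is the default. Basins overlapping the nucleus are kept and the
  nucleus-seeded component returned.
* **SLIC superpixels.** An in-package SLIC (localized k-means over color
  and position, grid-initialized, gradient-perturbed, connectivity
  enforced; `n_segments = 100`, `compactness = 10`). Superpixels are
  retained when their majority lies in the 3-px-dilated nucleus or their
  mean intensity is at most the cytoplasm estimate (mean intensity of the
  annulus around the nucleus) plus 0.05. Under-segmentation of the cell
  is preferred to leakage into red cells; the nucleus-seeded component is
  returned.

### Evaluation metrics

Jaccard `TP/(TP+FP+FN)` and Dice `2TP/(2TP+FP+FN)` with ground truth as
reference, plus sensitivity, specificity and precision. Two conventions
the literature leaves open: an empty-vs-empty comparison scores 1 (with a
warning), and ratios with zero denominators are reported as undefined and
excluded from batch means (zero-filling would bias averages downward).
Nucleus masks are scored against ground-truth label 255 and whole-cell
masks against labels {128, 255}.

## The synthetic fixtures

`generate_cell_image()` renders: a nucleus as a union of 1–4 overlapping
ellipses near the center; a cytoplasm blob as the morphological dilation
of the nucleus; annular red cells placed by rejection sampling, never
overwriting the cell (so ground truth is exact); and Gaussian noise,
clipped to [0, 1]. Class means default to 0.20 / 0.55 / 0.70 / 0.90
(nucleus / cytoplasm / red cell / background) so that `T_nc0 ≈ 1/3` falls
inside the nucleus–cytoplasm valley — the regime the method targets —
with noise σ = 0.03, well below half the smallest class gap. Colors are
per-class hues scaled so their BT.601 luminance equals the class mean
exactly, making the color → grayscale path reproduce the gray fixture.
When an unlucky shape draw leaves no room for the requested red cells,
the whole geometry is redrawn from a derived sub-seed, keeping the
generator deterministic per seed.

What the fixtures do **not** emulate: staining variability and texture
(chromatin granularity, cytoplasm granules), uneven illumination,
out-of-focus blur, overlapping WBCs, and platelets. Passing tests on
fixtures therefore demonstrate the pipeline's correctness and its behavior
under the stated intensity model, not performance on any real stained
dataset; on real data the histogram valley is shallower and thresholds
shift accordingly.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 120×120 images: 50
separated-regime and 20 touching-regime fixtures for the end-to-end
checks, 1,000 randomized triples for the branch rule, 100 images for the
Otsu oracle and 200 mask pairs for the metric identities. These sizes
exercise every code path while keeping a full run to tens of seconds on
one CPU; the operations scale linearly in pixel count and have been run
on 360×363 presets as well.

Other numerics: histograms use equal-width bins on [0, 1] with an
inclusive upper edge (counts always sum to the pixel count);
8-connectivity is used for every component operation (diagonal lobes of a
nucleus belong together); component labeling merges 4-connected labels
across diagonal adjacencies with a union–find; degenerate inputs
(constant images, empty masks, thresholds of 0 or 1) raise typed
conditions or warnings rather than returning silently wrong masks.

## Known limitations

* One cell per image is assumed; a second WBC is segmented or not purely
  by intensity and connectivity.
* The mean-intensity "contrast" between nucleus and cytoplasm is one
  reasonable definition among several; no claim is made that it matches
  any externally reported contrast figure.
* The SLIC implementation favors clarity over speed; it is comfortable at
  smear-crop sizes (~100–400 px per side) but is not optimized for
  megapixel images.
* The watershed fallback depends on the global Otsu foreground; on images
  whose background is not clearly the brightest class it can fail before
  markers are even placed.
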
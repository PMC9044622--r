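# lminseg

Automatic threshold estimation and white-blood-cell (WBC) segmentation for
single-cell blood-smear micrographs.

Differential counting and morphology assessment of leukocytes start from
segmenting each cell into nucleus, cytoplasm and background. On stained
smears the nucleus is the darkest structure, the cytoplasm sits at
intermediate intensity, and red blood cells (RBCs) and plasma are brighter.
`lminseg` implements a fully unsupervised, histogram-driven pipeline for
this setting, aimed at hematology image-analysis work where no training
data or GPU is available: each image supplies its own threshold.

## Method

**Nucleus.** For a grayscale image `A` with intensities in [0, 1], an
initial value

```
T_nc0 = Max(A)/n1 + Min(A)/n2        (defaults n1 = n2 = 3)
```

is computed; with a near-black minimum it sits near 1/3, inside the
nucleus–cytoplasm valley of typical smears. The histogram `h(x)` (256 bins)
is halved, its leading flat tail removed, the counts smoothed with a
Savitzky–Golay filter (window 11, order 3), and a cubic interpolating
spline `g(x)` fitted. Scanning `g` in increasing intensity gives the first
local maximum `x_c` and the following first local minimum `x_{c+1}`; if no
such pair exists the search segment is extended by 10% of the bins and the
scan repeats. Subject to `x_c < T_nc0`, the nucleus threshold is chosen by
a four-branch rule with margin `Er` (default 0.07):

| condition | threshold ε_t |
|---|---|
| `\|T_nc0 − x_{c+1}\| ≤ Er` | `(T_nc0 + x_{c+1}) / 2` |
| `\|T_nc0 − x_{c+1}\| > Er`, `T_nc0 > x_{c+1}` | `(T_nc0 + x_{c+1} + Er) / 2` |
| `\|T_nc0 − x_{c+1}\| > Er`, `T_nc0 < x_{c+1}` | `(T_nc0 + x_{c+1} − Er) / 2` |

Pixels with `f ≤ ε_t` form the nucleus; small objects are removed and
holes filled.

**Whole cell.** A family of `n` thresholds (default 10)

```
T_wbc^i = (Max(A) + T_nc0)/2 + er_i,   er_i spanning [Min(A), Max(A)/3]
```

produces `n` floor images `A_j = max(A, T_wbc^i)` whose pixel-wise mean
`A_wbc` flattens the cell interior while keeping the background bright.
`A_wbc` is binarized at its Otsu threshold (dark class = cell), cleaned
morphologically, and the component containing a seed pixel from the
segmented nucleus is extracted. The cytoplasm is the cell minus the
nucleus.

**Touching red cells.** When RBCs touch the WBC, two fallbacks replace the
averaging strategy: SLIC superpixels (retained by nucleus overlap and a
cytoplasm-informed intensity cut) and marker-controlled watershed on the
distance transform (markers at automatically chosen distance maxima,
basins merged across thick boundaries, nucleus-overlapping basins
retained).

**Evaluation.** Jaccard index `TP/(TP+FP+FN)`, Dice coefficient
`2TP/(2TP+FP+FN)`, sensitivity, specificity and precision against
tri-level ground truth (nucleus = 255, cytoplasm = 128, background = 0),
plus per-class batch summaries and predicted-vs-true size correlations.

A seeded synthetic-fixture generator (`fixture_spec()`,
`generate_cell_image()`, `generate_suite()`) renders multi-lobed nuclei,
cytoplasm blobs, annular RBCs (separated or touching) and noise, with
exact ground truth, so the whole pipeline is testable without any dataset
download.

## Worked example

```r
library(lminseg)

fx  <- generate_cell_image(fixture_spec(random_seed = 42))  # 120x120 smear
res <- segment_cell(fx$gray, pipeline_config())
print(res$estimate)
#> threshold estimate: epsilon_t = 0.2811 (branch c)
#>   T_nc0 = 0.3620, x_c = 0.1270, x_c+1 = 0.1301, Er = 0.070

ev <- evaluate_against_truth(res$nucleus, res$wbc, fx$mask)
#> nucleus: JI 1.0000 DSC 1.0000 | whole cell: JI 0.9983 DSC 0.9991
```

`T_nc0 = 0.362` is the initial value for this image (its maximum is near
1, its minimum near 0.09). The first histogram peak (`x_c = 0.127`, the
nucleus mode) precedes it, and the following minimum lies more than
`Er = 0.07` below it, so the rule takes its third branch and places the
nucleus threshold at `ε_t = 0.281` — between the nucleus (0.20) and
cytoplasm (0.55) class means. The resulting masks agree with the exact
ground truth at Dice 1.000 (nucleus) and 0.999 (whole cell); the Otsu
threshold on the averaged reconstruction was 0.914.

A shell front end wrapping the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lminseg.R", package = "lminseg"))') \
    simulate --n 5 --regime separated --seed 42 --outdir fixtures/
```

with further subcommands `nucleus`, `cell` and `eval`.

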
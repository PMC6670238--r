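# RGCount

Semi-automated counting of retinal ganglion cells (RGCs) in fluorescence
flat-mount retina images, for labs quantifying RGC loss in optic
neuropathies and neuroinflammatory disease models (e.g. experimental
autoimmune encephalomyelitis, EAE). The package reimplements a
size-segmentation counting workflow for Brn3a-labeled whole mounts: the
user marks the optic nerve head and cut axes, twelve 350 × 350 µm segments
are sampled (4 quadrants × central/middle/peripheral eccentricity bands),
each segment is counted automatically, and densities in cells/mm² are
averaged per retina and compared across groups.

## The counting algorithm

Each segment passes through:

1. **Filtering** — Gaussian smoothing, σ = 1 µm by default.
2. **Thresholding** — Otsu's between-class-variance-maximizing threshold on
   a 256-bin histogram of the observed intensity range, or a user-defined
   threshold.
3. **Binarization and labeling** — strict `intensity > t` foreground,
   optional hole filling, connected components under 8- (or 4-)
   connectivity.
4. **Size exclusion** — objects with area ≤ 20 µm² are discarded as
   staining noise.
5. **Cluster splitting** — the mean single-cell area `m` is estimated by a
   robust fixed point (median initialization, reclassify, interquartile
   trimmed mean of the putative singles, iterate); an object of area `A` is
   a single cell if `A ≤ 1.5 m`, otherwise a cluster of overlapping cells
   contributing

   &nbsp;&nbsp;&nbsp;&nbsp;`max(2, ⌊A/m + 0.5⌋)`

   cells (round half up). The segment count is the number of singles plus
   the summed cluster estimates, and the density is `count / (0.35 mm)²`.

Group statistics follow the original study design: two-tailed unpaired
Student's *t* test (Welch optional), one-way ANOVA with Tukey's HSD,
Spearman rank correlation between per-animal density and the 0–5 EAE
behavior score (exact permutation *p* for n ≤ 9, *t* approximation above),
and paired automated-vs-manual agreement.

A calibrated synthetic scene generator with exact ground truth (cell
positions, radii, touching-pair memberships) makes the whole pipeline
testable without microscope data.

## Worked example

```r
library(RGCount)

spec <- SyntheticSpec(density = 3683, seed = 1)   # a control-like segment
scene <- generateSegment(spec)
scene$truth
#> GroundTruth: 451 cells (44 in touching pairs) on 350 um square

sc <- countSegment(scene$image)
sc
#> SegmentCount: 502 cells (326 singles, 67 clusters, 0 noise objects)
#>   mean single-cell area 74.41 um^2, threshold 101.4

cellDensity(nTotalCells(sc), 350)
#> [1] 4097.959
```

451 cells/segment is 3681.6 cells/mm²; the automated count of 502 (4098
cells/mm²) illustrates the method's documented overcount at high, confluent
densities — at this packing, large somata preferentially touch their
neighbors, which both merges them into clusters and biases the single-cell
area estimate low (74.4 µm² here versus ~81 µm² for an isolated 5 µm-radius
soma at this threshold). On clean, well-separated scenes recovery is exact:

```r
scene <- generateSegment(SyntheticSpec(density = 1600, cellRadiusCV = 0,
                                       overlapPairFraction = 0, noiseSd = 2.8,
                                       minSeparation = 14, seed = 7))
nTotalCells(countSegment(scene$image)) == trueCount(scene$truth)
#> [1] TRUE
```

The methods vignette (`vignettes/rgc-counting.Rmd`) derives both behaviors
quantitatively.

For real images: `readMosaic()` (TIFF, with z-stack maximum-intensity
projection via `projectStack()`), `buildLayout()` + `sampleRegions()` +
`extractSegment()` for the twelve segments, `summarizeRetina()` for the
per-retina density, and `compareTwoGroups()` / `compareMultiGroups()` /
`correlateWithScore()` / `agreementAutoManual()` for the statistics. A
command-line front end with `count`, `simulate`, `compare` and `agreement`
subcommands lives at `inst/scripts/rgcount.R`; every run writes a manifest
recording the exact configuration and seed.

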
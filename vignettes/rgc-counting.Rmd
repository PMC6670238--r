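---
title: "Counting retinal ganglion cells by size segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting retinal ganglion cells by size segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RGCount)
```

## The measurement problem

Retinal ganglion cell (RGC) loss is the structural endpoint of many optic
neuropathies and of neuroinflammatory models such as EAE. The standard
readout is the density of immunolabeled somata (Brn3a, RBPMS) in the
ganglion cell layer of a flat-mounted retina, in cells/mm². Manual counting
is slow and subjective; fully automatic counting is fragile because somata
overlap. The compromise implemented here is *semi-automated size
segmentation*: a human supplies the geometry (optic nerve head position,
cut-axis orientation, retinal radius, optionally a threshold), and a
deterministic algorithm does everything else.

## Sampling geometry

A flat mount is four lobes around the optic nerve head. `sampleRegions()`
places one axis-aligned square segment per quadrant and eccentricity band —
12 segments of 350 × 350 µm — on the quadrant bisectors at fixed fractions
of the outer radius (defaults 0.25, 0.55, 0.85). The fractions are a
convention of this package: the source workflow shows central, middle and
peripheral sampling locations but does not parameterize them, and evenly
spaced mid-band radii reproduce that design deterministically. Segments are
axis-aligned (no rotation with the bisector) so extraction is a verbatim
pixel crop with no interpolation; with the default band spacing this
requires an outer radius of at least ~1.65 mm, which a mouse retinal flat
mount satisfies. Eccentricity is measured from the user-marked optic nerve
head, not the image centroid, because mounts are rarely centered in the
frame.

The per-retina density is the arithmetic mean of the 12 segment densities;
regional means average the four quadrants within a band.

## The detector

For a calibrated segment (µm/pixel known) the stages are:

* **Filtering.** Gaussian smoothing with σ = `smoothingRadius` (default
  1 µm, about two pixels at 20×). σ = 0 is the exact identity, which keeps
  pixel-level tests sharp. An optional white-tophat (off by default)
  suppresses slowly varying background.
* **Thresholding.** `automatic` mode maximizes between-class variance
  (Otsu) on a 256-bin histogram spanning the observed range, then places
  the cut midway between the nearest data values on either side, so the
  binarization is exactly the optimal split and is invariant under any
  positive rescaling of the intensities. A constant segment is an *error*
  in automatic mode, not a zero count: a flat image is an acquisition
  failure. `manual` mode passes the user threshold through verbatim.
* **Binarization.** Strict `intensity > t` (fixes boundary-pixel
  ambiguity); optional filling of enclosed background holes (dim nuclear
  centers).
* **Labeling.** Connected components by a two-pass run-length union-find,
  8-connectivity by default (round somata rarely touch only diagonally);
  4-connectivity is available for sensitivity analysis. Outer contours are
  traced (Moore neighborhood) for overlays.
* **Size exclusion.** Objects with area ≤ `minObjectArea` (default 20 µm²)
  are noise: a 10 µm-diameter soma is ~79 µm², so the cutoff removes
  speckle without touching real cells.
* **Cluster splitting.** With mean single-cell area `m`, an object of area
  `A` is a single cell if `A ≤ 1.5 m` and otherwise a cluster contributing
  `max(2, round_half_up(A/m))` cells. Half rounds up (2.5 → 3), and an
  identified cluster never contributes fewer than two cells. The 1.5 factor
  makes the classification consistent with the rounding: any area just
  above the single/cluster boundary already rounds to 2.

`m` itself is estimated from the segment: initialize with the median area
of all objects above the noise cutoff, classify, re-estimate as the
interquartile-trimmed mean of the current singles, and iterate to a fixed
point (at most 10 rounds; the loop stops at the first repeated
membership). The trimmed mean keeps clusters and debris from inflating the
average.

The detector contains no randomness: identical segment and configuration
give a bit-identical result, and counts are invariant under right-angle
rotations, mirroring, and intensity gain (automatic mode).

## The synthetic generator

`generateSegment()` renders scenes with exact ground truth, emulating
Brn3a-like nuclear/somal staining at 20×:

* cell radii Normal(5 µm, CV 0.15), the planted count deterministic at
  `round(density × area)` so exact-recovery tests are sharp (a Poisson
  count would blur them);
* somata as smooth radial profiles `exp(−ln 2 · (d/r)^10)` — half maximum
  exactly at the planted radius, effectively zero beyond 1.3 r. The
  shoulder spans several pixels (thresholding stays non-trivial) but the
  halo is short, so neighboring somata do not fuse through their rendering
  tails and a mid-contrast threshold recovers discs of the planted radii;
* a fraction of cells (default 10%) in touching pairs at center distance
  1.2 radii — the merged object is ~1.7 single areas, the regime the
  splitting rule addresses; all other cells respect a hard minimum
  separation (default 12 µm), placed by dart throwing with a retry cap;
* constant foreground level 180 over background 40, additive Gaussian
  noise SD 7 (5% of contrast), clipped at zero. No shot noise, vignetting,
  stitching seams or non-RGC background cells are modeled — passing tests
  certify the algorithm on idealized scenes, not performance on real
  tissue.

The 12 µm separation default deserves a note: at the control-retina
densities this package models (~3700 cells/mm², i.e. ~450 cells per
segment), 12 µm exclusion discs already occupy ~84% of their random
sequential packing limit. Larger separations are *geometrically
infeasible* — real tissue at these densities necessarily contains touching
somata beyond the planted pairs.

`generateRetina()` plants an eccentricity gradient (central > middle >
peripheral) in the 12 standard segments of a whole-mount canvas, and
`generateCohort()` draws per-animal densities around group means (defaults:
11 "diseased" animals at 2272 cells/mm² and 8 controls at 3683, with
SEM-derived spreads) and behavior scores from a decreasing density–score
map, clamped to the 0–5 clinical scale and snapped to its 0.5 steps.

## What the validation shows — including a bias the method really has

The test suite and `scripts/acceptance.R` establish, on one CPU in minutes
(12 segments per synthetic retina, 20 seeds for exactness, 5 retinas for
the agreement check):

* **Exactness on clean scenes.** Uniform-size, well-separated cells, low
  noise: the count equals ground truth exactly across all seeds tested.
* **Cluster arithmetic.** On scenes of disjoint rectangle archetypes the
  pipeline total equals the analytic
  `Σ max(2, round(area/m))` computed directly from the known areas.
* **Statistics.** The t, ANOVA/Tukey and Spearman wrappers agree with the
  reference implementations to better than six significant digits; the
  exact-permutation Spearman p (used for n ≤ 9, where cohorts are small
  and ties are common) matches the classical exact distribution where both
  are defined.
* **A real overcount under realistic conditions.** With radius CV 0.15 and
  10% touching pairs at the study's printed densities, recovered means run
  ~9–12% above the planted truth. The acceptance suite reports this
  honestly rather than hiding it, because it is a property of the *method*,
  not an implementation defect, with two mechanisms the package's own
  object-level audit isolates:
  1. with 15% radius CV, ~6–7% of true singles have area above 1.5 m and
     are counted as two cells — the single/cluster boundary sits inside
     the upper tail of the single-area distribution, and rounding never
     subtracts what it adds (a cluster is floored at 2);
  2. at ~450 cells per segment, contact between somata is unavoidable and
     size-assortative — larger cells merge preferentially — so the singles
     that remain for estimating `m` are a small-biased sample (their
     median radius runs ~0.7 µm below that of the cells absorbed into
     clusters), deflating `m` and inflating every cluster ratio.

  Both effects shrink as density or size dispersion falls; the same
  pipeline is exact when somata are resolvable. Users comparing groups
  should note that a shared multiplicative bias largely cancels in
  *relative* comparisons (percent loss, group ratios) but not in absolute
  densities, and that a paired automated-vs-manual comparison on confluent
  central retina will detect it.

## Numerical and design choices

* Round-half-up (`⌊x + 0.5⌋`) everywhere a count is rounded: deterministic
  ties, no banker's rounding surprises.
* The Otsu cut is returned as the midpoint of the empirical gap between
  classes, making "strictly above threshold" reproducible across rescaled
  data.
* Z-stacks are counted on a maximum-intensity projection by default
  (somata are bright and sparse along z; the maximum preserves them across
  focal planes); mean projection is available.
* Pixel calibration is always supplied by the user. TIFF resolution tags
  vary too much across microscopes to be trusted silently.
* Equal-variance t test by default, matching the classical unpaired
  Student test of the original analyses; Welch by flag.
* Degenerate inputs have defined behavior: identical groups give p = 1,
  zero-variance groups with different means give p = 0, degenerate ranks
  are an error rather than NaN.
* The agreement check is a paired t test on per-segment counts (the unit a
  masked manual recount produces), with a per-band breakdown.
* Per-retina densities use one specified eye; averaging both eyes is the
  caller's choice (the flat-mount workflow this models used one eye per
  animal).

## Limitations

No watershed or learned instance segmentation — objects are split by area
ratio only, so geometry (dumbbell vs disc) is ignored. No multi-channel
colocalization, no stitching or flat-field correction, no automatic optic
nerve head detection. The synthetic scenes are idealized; absolute
performance on real tissue depends on staining quality and should be
anchored by a masked manual count on a subset, exactly as the original
workflow did.
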
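#' @include AllGenerics.R
NULL

## controlled vocabularies shared by the tabular formats
.eccLevels <- c("central", "middle", "peripheral")
.eyeLevels <- c("left", "right")
.groupLevels <- c("EAE", "CFA", "naive")

# ---------------------------------------------------------------------------
# MosaicImage / ZStack
# ---------------------------------------------------------------------------

#' Calibrated single-channel fluorescence image
#'
#' A 2-D grid of non-negative intensities (arbitrary units) with an isotropic
#' pixel calibration in micrometres per pixel. This is the substrate of the
#' whole pipeline: either a stitched mosaic of a whole flat-mounted retina or
#' a single extracted 350 x 350 um analysis segment.
#'
#' @slot pixels numeric matrix of intensities; rows index y, columns x.
#' @slot pixelSize micrometres per pixel, > 0.
#' @slot bitDepth acquisition bit depth (informational; may be \code{NA}).
#'
#' @seealso \code{\link{readMosaic}}, \code{\link{extractSegment}},
#'   \code{\link{countSegment}}
#' @export
setClass("MosaicImage",
  slots = c(pixels = "matrix", pixelSize = "numeric", bitDepth = "numeric"))

setValidity("MosaicImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (anyNA(p)) return("pixels contain NA")
  if (min(p) < 0) return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/pixel)")
  TRUE
})

#' @rdname MosaicImage-class
#' @param pixels,pixelSize,bitDepth see slots.
#' @return \code{MosaicImage()} returns a validated object.
#' @export
MosaicImage <- function(pixels, pixelSize, bitDepth = NA_real_) {
  if (is.integer(pixels)) storage.mode(pixels) <- "double"
  new("MosaicImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      bitDepth = as.numeric(bitDepth))
}

#' Ordered stack of equally shaped focal planes
#'
#' @slot planes list of numeric matrices, all of identical shape.
#' @slot zStep axial distance between planes in micrometres.
#' @slot pixelSize lateral calibration in micrometres per pixel.
#' @seealso \code{\link{projectStack}}
#' @export
setClass("ZStack",
  slots = c(planes = "list", zStep = "numeric", pixelSize = "numeric"))

setValidity("ZStack", function(object) {
  pl <- object@planes
  if (length(pl) < 1L) return("a ZStack needs at least one plane")
  d <- dim(pl[[1L]])
  for (p in pl) {
    if (!is.matrix(p) || !is.numeric(p)) return("planes must be numeric matrices")
    if (!identical(dim(p), d)) return("all planes must share one shape")
    if (anyNA(p) || min(p) < 0) return("plane intensities must be non-negative")
  }
  if (!is.finite(object@zStep) || object@zStep <= 0)
    return("zStep must be > 0 (um)")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0 (um/pixel)")
  TRUE
})

#' @rdname ZStack-class
#' @param planes,zStep,pixelSize see slots.
#' @export
ZStack <- function(planes, zStep, pixelSize) {
  planes <- lapply(planes, function(p) { storage.mode(p) <- "double"; p })
  new("ZStack", planes = planes, zStep = as.numeric(zStep),
      pixelSize = as.numeric(pixelSize))
}

# ---------------------------------------------------------------------------
# Sampling geometry
# ---------------------------------------------------------------------------

#' Four-quadrant sampling layout over a flat-mounted retina
#'
#' The geometry over which the twelve analysis segments are placed: the
#' user-marked optic-nerve-head position, the two cut axes that partition the
#' mount into four quadrants, and the outer radius of the tissue. Angles are
#' measured in radians from the +x (column) axis towards the +y (row) axis.
#'
#' @slot center (x, y) optic-nerve-head position in pixels.
#' @slot quadrantAxes two angles (radians); together with their opposites
#'   they cut the disc into four sectors.
#' @slot outerRadius micrometres from center to the retinal edge.
#' @slot pixelSize micrometres per pixel of the underlying image.
#' @slot imageDim (nrow, ncol) of the underlying image.
#' @seealso \code{\link{buildLayout}}, \code{\link{sampleRegions}}
#' @export
setClass("RetinaLayout",
  slots = c(center = "numeric", quadrantAxes = "numeric",
            outerRadius = "numeric", pixelSize = "numeric",
            imageDim = "integer"))

setValidity("RetinaLayout", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be (x, y) in pixels")
  if (length(object@quadrantAxes) != 2L || !all(is.finite(object@quadrantAxes)))
    return("quadrantAxes must be two angles in radians")
  a <- sort((object@quadrantAxes %% pi))
  if (abs(a[1L] - a[2L]) < 1e-9)
    return("quadrant axes are collinear; they must cut four sectors")
  if (!is.finite(object@outerRadius) || object@outerRadius <= 0)
    return("outerRadius must be > 0 (um)")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0")
  if (length(object@imageDim) != 2L || any(object@imageDim < 1L))
    return("imageDim must be (nrow, ncol)")
  d <- object@imageDim
  x <- object@center[1L]; y <- object@center[2L]
  if (x < 1 || x > d[2L] || y < 1 || y > d[1L])
    return("center lies outside the image")
  TRUE
})

#' One of the twelve square analysis segments
#'
#' An axis-aligned square region of interest labeled by quadrant (1-4) and
#' eccentricity band (central / middle / peripheral). \code{origin} is the
#' (x, y) pixel index of the top-left corner; the ROI spans \code{sidePx}
#' pixels in each direction.
#'
#' @slot quadrant integer 1-4.
#' @slot eccentricity one of \code{"central"}, \code{"middle"},
#'   \code{"peripheral"}.
#' @slot origin integer (x, y) of the top-left pixel.
#' @slot sidePx side length in pixels.
#' @slot sideUm side length in micrometres (default sampling uses 350).
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("SegmentROI",
  slots = c(quadrant = "integer", eccentricity = "character",
            origin = "integer", sidePx = "integer", sideUm = "numeric",
            pixelSize = "numeric"))

setValidity("SegmentROI", function(object) {
  if (!(object@quadrant %in% 1:4)) return("quadrant must be 1..4")
  if (!(object@eccentricity %in% .eccLevels))
    return("eccentricity must be central/middle/peripheral")
  if (length(object@origin) != 2L || any(object@origin < 1L))
    return("origin must be positive (x, y) pixel indices")
  if (object@sidePx < 1L) return("sidePx must be >= 1")
  if (!is.finite(object@sideUm) || object@sideUm <= 0)
    return("sideUm must be > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Detector configuration and result
# ---------------------------------------------------------------------------

#' Configuration of the size-segmentation detector
#'
#' @slot smoothingRadius Gaussian pre-filter sigma in micrometres; 0 disables
#'   filtering (the detector then sees the raw segment).
#' @slot thresholdMode \code{"automatic"} (Otsu on the segment histogram) or
#'   \code{"manual"}.
#' @slot manualThreshold intensity used verbatim in manual mode.
#' @slot connectivity pixel neighborhood for component labeling, 4 or 8.
#' @slot minObjectArea size-exclusion cutoff in um^2; objects at or below it
#'   are classified as noise.
#' @slot clusterFactor objects larger than \code{clusterFactor} times the
#'   mean single-cell area are treated as overlapping-cell clusters.
#' @slot fillHoles fill enclosed background holes after binarization.
#' @slot tophatRadius radius (um) of an optional white-tophat background
#'   suppression applied before smoothing; 0 (default) disables it.
#' @seealso \code{\link{countSegment}}
#' @export
setClass("DetectorConfig",
  slots = c(smoothingRadius = "numeric", thresholdMode = "character",
            manualThreshold = "numeric", connectivity = "integer",
            minObjectArea = "numeric", clusterFactor = "numeric",
            fillHoles = "logical", tophatRadius = "numeric"))

setValidity("DetectorConfig", function(object) {
  if (!is.finite(object@smoothingRadius) || object@smoothingRadius < 0)
    return("smoothingRadius must be >= 0")
  if (!(object@thresholdMode %in% c("automatic", "manual")))
    return("thresholdMode must be 'automatic' or 'manual'")
  if (object@thresholdMode == "manual" && !is.finite(object@manualThreshold))
    return("manual mode requires a finite manualThreshold")
  if (!(object@connectivity %in% c(4L, 8L)))
    return("connectivity must be 4 or 8")
  if (!is.finite(object@minObjectArea) || object@minObjectArea < 0)
    return("minObjectArea must be >= 0 (um^2)")
  if (!is.finite(object@clusterFactor) || object@clusterFactor <= 1)
    return("clusterFactor must be > 1")
  if (!is.finite(object@tophatRadius) || object@tophatRadius < 0)
    return("tophatRadius must be >= 0")
  TRUE
})

#' @rdname DetectorConfig-class
#' @param smoothingRadius,thresholdMode,manualThreshold,connectivity see slots.
#' @param minObjectArea,clusterFactor,fillHoles,tophatRadius see slots.
#' @return \code{DetectorConfig()} returns a validated configuration with the
#'   package defaults: 1 um Gaussian smoothing, automatic (Otsu)
#'   thresholding, 8-connectivity, 20 um^2 size exclusion, cluster factor
#'   1.5, hole filling on.
#' @export
DetectorConfig <- function(smoothingRadius = 1, thresholdMode = "automatic",
                           manualThreshold = NA_real_, connectivity = 8L,
                           minObjectArea = 20, clusterFactor = 1.5,
                           fillHoles = TRUE, tophatRadius = 0) {
  new("DetectorConfig", smoothingRadius = as.numeric(smoothingRadius),
      thresholdMode = thresholdMode,
      manualThreshold = as.numeric(manualThreshold),
      connectivity = as.integer(connectivity),
      minObjectArea = as.numeric(minObjectArea),
      clusterFactor = as.numeric(clusterFactor),
      fillHoles = isTRUE(fillHoles), tophatRadius = as.numeric(tophatRadius))
}

#' Detection result for one analysis segment
#'
#' @slot objects data frame with one row per labeled connected component:
#'   \code{objectId}, \code{areaPx}, \code{areaUm2}, \code{centroidX},
#'   \code{centroidY}, \code{label} (noise/single/cluster) and
#'   \code{estimatedCells} (0 for noise, 1 for singles, >= 2 for clusters).
#' @slot boundaries list (one entry per object) of two-column (x, y) matrices
#'   tracing each component's outer contour in order.
#' @slot meanSingleArea estimated mean single-cell area in um^2 (\code{NA}
#'   when no object survives size exclusion).
#' @slot nSingles,nClusterObjects,nTotalCells counts; \code{nTotalCells} is
#'   the number of singles plus the summed cluster estimates.
#' @slot thresholdUsed the intensity threshold actually applied.
#' @slot pixelSize calibration of the counted segment.
#' @seealso \code{\link{countSegment}}, \code{\link{objectTable}}
#' @export
setClass("SegmentCount",
  slots = c(objects = "data.frame", boundaries = "list",
            meanSingleArea = "numeric", nSingles = "integer",
            nClusterObjects = "integer", nTotalCells = "integer",
            thresholdUsed = "numeric", pixelSize = "numeric"))

setValidity("SegmentCount", function(object) {
  o <- object@objects
  need <- c("objectId", "areaPx", "areaUm2", "centroidX", "centroidY",
            "label", "estimatedCells")
  if (!all(need %in% names(o))) return("objects is missing required columns")
  if (nrow(o)) {
    if (!all(o$label %in% c("noise", "single", "cluster")))
      return("object labels must be noise/single/cluster")
    if (any(o$estimatedCells[o$label == "noise"] != 0L) ||
        any(o$estimatedCells[o$label == "single"] != 1L) ||
        any(o$estimatedCells[o$label == "cluster"] < 2L))
      return("estimatedCells inconsistent with labels")
  }
  nS <- sum(o$label == "single")
  nC <- sum(o$label == "cluster")
  tot <- nS + sum(o$estimatedCells[o$label == "cluster"])
  if (object@nSingles != nS || object@nClusterObjects != nC ||
      object@nTotalCells != tot)
    return("count conservation violated: nTotalCells must equal nSingles plus summed cluster estimates")
  TRUE
})

# ---------------------------------------------------------------------------
# Per-retina summary
# ---------------------------------------------------------------------------

#' Per-retina density summary over the twelve segments
#'
#' @slot densities data frame with columns \code{quadrant},
#'   \code{eccentricity}, \code{count}, \code{density} (cells/mm^2), one row
#'   per (quadrant, eccentricity).
#' @slot meanDensity arithmetic mean of the 12 densities; the per-retina RGC
#'   density estimate.
#' @slot regionalMeans named numeric (central, middle, peripheral): mean of
#'   the four quadrant densities in each band.
#' @slot animalId,eye identifiers carried through to tables.
#' @slot sideUm segment side used for the densities.
#' @seealso \code{\link{summarizeRetina}}
#' @export
setClass("RetinaSummary",
  slots = c(densities = "data.frame", meanDensity = "numeric",
            regionalMeans = "numeric", animalId = "character",
            eye = "character", sideUm = "numeric"))

setValidity("RetinaSummary", function(object) {
  d <- object@densities
  if (nrow(d) != 12L) return("a retina summary needs exactly 12 segments")
  key <- paste(d$quadrant, d$eccentricity)
  if (anyDuplicated(key)) return("duplicate (quadrant, eccentricity) labels")
  if (abs(object@meanDensity - mean(d$density)) > 1e-8 * max(1, abs(object@meanDensity)))
    return("meanDensity must be the mean of the 12 densities")
  for (e in .eccLevels) {
    m <- mean(d$density[d$eccentricity == e])
    if (abs(object@regionalMeans[[e]] - m) > 1e-8 * max(1, abs(m)))
      return("regionalMeans must be the per-band means")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Synthetic scenes
# ---------------------------------------------------------------------------

#' Parameters of a synthetic flat-mount segment
#'
#' Defaults emulate Brn3a-stained RGC somata imaged at 20x: ~10 um diameter
#' cells (radius 5 um, 15% radius CV), bright somata (intensity 180) over a
#' noisy background (level 40, additive Gaussian noise SD 7, i.e. 5% of the
#' 140-unit contrast), 10% of cells placed as touching overlapping pairs and
#' the remainder separated by at least 12 um so that unpaired somata are
#' optically resolvable (the packing limit of a 350 um segment at the
#' densities this package models).
#'
#' @slot density planted cell density in cells/mm^2.
#' @slot sideUm segment edge length in micrometres (350 by default).
#' @slot pixelSize micrometres per pixel (0.5 by default).
#' @slot cellRadiusMean,cellRadiusCV mean soma radius (um) and fractional SD.
#' @slot cellIntensity,backgroundLevel mean foreground / background levels.
#' @slot noiseSd SD of the additive Gaussian noise (clipped at zero).
#' @slot overlapPairFraction fraction of cells placed as touching pairs at a
#'   center distance of 1.2 soma radii.
#' @slot minSeparation minimum center distance (um) between non-paired cells.
#' @slot seed integer; fixes the full scene.
#' @seealso \code{\link{generateSegment}}
#' @export
setClass("SyntheticSpec",
  slots = c(density = "numeric", sideUm = "numeric", pixelSize = "numeric",
            cellRadiusMean = "numeric", cellRadiusCV = "numeric",
            cellIntensity = "numeric", backgroundLevel = "numeric",
            noiseSd = "numeric", overlapPairFraction = "numeric",
            minSeparation = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!is.finite(object@density) || object@density < 0)
    return("density must be >= 0")
  if (object@sideUm <= 0 || object@pixelSize <= 0)
    return("sideUm and pixelSize must be > 0")
  if (object@cellRadiusMean <= 0 || object@cellRadiusCV < 0)
    return("cellRadiusMean must be > 0 and cellRadiusCV >= 0")
  if (object@overlapPairFraction < 0 || object@overlapPairFraction > 1)
    return("overlapPairFraction must be in [0, 1]")
  if (object@cellIntensity <= object@backgroundLevel)
    return("cellIntensity must exceed backgroundLevel")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@minSeparation < 0) return("minSeparation must be >= 0")
  TRUE
})

#' @rdname SyntheticSpec-class
#' @param density,sideUm,pixelSize,cellRadiusMean,cellRadiusCV see slots.
#' @param cellIntensity,backgroundLevel,noiseSd see slots.
#' @param overlapPairFraction,minSeparation,seed see slots.
#' @export
SyntheticSpec <- function(density, sideUm = 350, pixelSize = 0.5,
                          cellRadiusMean = 5, cellRadiusCV = 0.15,
                          cellIntensity = 180, backgroundLevel = 40,
                          noiseSd = 7, overlapPairFraction = 0.10,
                          minSeparation = 12, seed = 1L) {
  new("SyntheticSpec", density = as.numeric(density),
      sideUm = as.numeric(sideUm), pixelSize = as.numeric(pixelSize),
      cellRadiusMean = as.numeric(cellRadiusMean),
      cellRadiusCV = as.numeric(cellRadiusCV),
      cellIntensity = as.numeric(cellIntensity),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseSd = as.numeric(noiseSd),
      overlapPairFraction = as.numeric(overlapPairFraction),
      minSeparation = as.numeric(minSeparation), seed = as.integer(seed))
}

#' Ground truth of a synthetic segment
#'
#' @slot centers n x 2 matrix of true cell centers in micrometres (x, y from
#'   the segment's top-left corner).
#' @slot radii true soma radii in micrometres.
#' @slot pairId integer pair membership (\code{NA} for unpaired cells; both
#'   members of a touching pair share an id).
#' @slot sideUm segment edge length.
#' @export
setClass("GroundTruth",
  slots = c(centers = "matrix", radii = "numeric", pairId = "integer",
            sideUm = "numeric"))

setValidity("GroundTruth", function(object) {
  n <- nrow(object@centers)
  if (ncol(object@centers) != 2L && n > 0L) return("centers must be n x 2")
  if (length(object@radii) != n || length(object@pairId) != n)
    return("radii and pairId must match centers")
  p <- object@pairId[!is.na(object@pairId)]
  if (length(p) && any(table(p) != 2L)) return("pairs must have two members")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "MosaicImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MosaicImage: %d x %d px (%.1f x %.1f um), %.4g um/px\n",
              d[1L], d[2L], d[1L] * object@pixelSize, d[2L] * object@pixelSize,
              object@pixelSize))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@planes[[1L]])
  cat(sprintf("ZStack: %d planes of %d x %d px, z-step %.3g um, %.4g um/px\n",
              length(object@planes), d[1L], d[2L], object@zStep,
              object@pixelSize))
})

setMethod("show", "RetinaLayout", function(object) {
  cat(sprintf(
    "RetinaLayout: center (%.1f, %.1f) px, outer radius %.0f um,\n  axes %.1f / %.1f deg, image %d x %d px @ %.4g um/px\n",
    object@center[1L], object@center[2L], object@outerRadius,
    object@quadrantAxes[1L] * 180 / pi, object@quadrantAxes[2L] * 180 / pi,
    object@imageDim[1L], object@imageDim[2L], object@pixelSize))
})

setMethod("show", "SegmentROI", function(object) {
  cat(sprintf("SegmentROI: quadrant %d, %s; origin (%d, %d) px, %d px (%.0f um) square\n",
              object@quadrant, object@eccentricity, object@origin[1L],
              object@origin[2L], object@sidePx, object@sideUm))
})

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig:\n")
  cat(sprintf("  smoothingRadius %.3g um | threshold %s%s | connectivity %d\n",
              object@smoothingRadius, object@thresholdMode,
              if (object@thresholdMode == "manual")
                sprintf(" (%.4g)", object@manualThreshold) else "",
              object@connectivity))
  cat(sprintf("  minObjectArea %.3g um^2 | clusterFactor %.3g | fillHoles %s | tophat %.3g um\n",
              object@minObjectArea, object@clusterFactor, object@fillHoles,
              object@tophatRadius))
})

setMethod("show", "SegmentCount", function(object) {
  o <- object@objects
  cat(sprintf("SegmentCount: %d cells (%d singles, %d clusters, %d noise objects)\n",
              object@nTotalCells, object@nSingles, object@nClusterObjects,
              sum(o$label == "noise")))
  cat(sprintf("  mean single-cell area %.4g um^2, threshold %.4g\n",
              object@meanSingleArea, object@thresholdUsed))
})

setMethod("show", "RetinaSummary", function(object) {
  cat(sprintf("RetinaSummary [%s, %s eye]: mean density %.1f cells/mm^2\n",
              object@animalId, object@eye, object@meanDensity))
  cat(sprintf("  central %.1f | middle %.1f | peripheral %.1f\n",
              object@regionalMeans[["central"]],
              object@regionalMeans[["middle"]],
              object@regionalMeans[["peripheral"]]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %.0f cells/mm^2 on %.0f um square @ %.3g um/px (seed %d)\n",
              object@density, object@sideUm, object@pixelSize, object@seed))
  cat(sprintf("  radius %.3g um (CV %.2g), contrast %.3g over %.3g, noise SD %.3g\n",
              object@cellRadiusMean, object@cellRadiusCV,
              object@cellIntensity - object@backgroundLevel,
              object@backgroundLevel, object@noiseSd))
  cat(sprintf("  %.0f%% of cells in touching pairs, min separation %.3g um\n",
              100 * object@overlapPairFraction, object@minSeparation))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells (%d in touching pairs) on %.0f um square\n",
              nrow(object@centers), sum(!is.na(object@pairId)), object@sideUm))
})

# ---------------------------------------------------------------------------
# accessor methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("pixels", "MosaicImage", function(object) object@pixels)

#' @rdname accessors
setMethod("pixelSize", "MosaicImage", function(object) object@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "ZStack", function(object) object@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "SegmentROI", function(object) object@pixelSize)

#' @rdname accessors
setMethod("planes", "ZStack", function(object) object@planes)

#' @rdname accessors
setMethod("nTotalCells", "SegmentCount", function(object) object@nTotalCells)

#' @rdname accessors
setMethod("meanSingleArea", "SegmentCount", function(object) object@meanSingleArea)

#' @rdname accessors
setMethod("thresholdUsed", "SegmentCount", function(object) object@thresholdUsed)

#' @rdname accessors
setMethod("objectTable", "SegmentCount", function(object) object@objects)

#' @rdname accessors
setMethod("trueCount", "GroundTruth", function(object) nrow(object@centers))

#' @rdname accessors
setMethod("meanDensity", "RetinaSummary", function(object) object@meanDensity)

#' @rdname accessors
setMethod("regionalMeans", "RetinaSummary", function(object) object@regionalMeans)

#' @describeIn MosaicImage-class image dimensions (nrow, ncol).
#' @export
setMethod("dim", "MosaicImage", function(x) dim(x@pixels))
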
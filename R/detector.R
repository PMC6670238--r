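#' @include AllClasses.R
NULL

#' Pre-filter a segment
#'
#' Gaussian smoothing with sigma \code{smoothingRadius} (in micrometres,
#' converted to pixels through the calibration), preceded by an optional
#' white-tophat background suppression. A smoothing radius of zero returns
#' the input unchanged, which keeps pixel-exact tests meaningful.
#'
#' @param segment a calibrated \linkS4class{MosaicImage}.
#' @param config a \linkS4class{DetectorConfig}.
#' @return a \linkS4class{MosaicImage} of the same shape and calibration.
#' @export
preprocessSegment <- function(segment, config = DetectorConfig()) {
  stopifnot(is(segment, "MosaicImage"), is(config, "DetectorConfig"))
  p <- pixels(segment)
  ps <- pixelSize(segment)
  if (config@tophatRadius > 0) {
    rpx <- max(1L, as.integer(roundHalfUp(config@tophatRadius / ps)))
    kern <- makeBrush(2L * rpx + 1L, shape = "disc")
    p <- whiteTopHat(p, kern)
  }
  if (config@smoothingRadius > 0) {
    p <- gblur(p, sigma = config@smoothingRadius / ps)
    p[p < 0] <- 0
  }
  MosaicImage(p, ps, segment@bitDepth)
}

#' Compute the binarization threshold
#'
#' Manual mode returns the user-defined threshold verbatim; automatic mode
#' maximizes the between-class intensity variance (Otsu) on a 256-bin
#' histogram over the observed range, which makes the threshold covariant
#' with any positive rescaling of the intensities.
#'
#' @param segment a \linkS4class{MosaicImage} (usually the preprocessed one).
#' @param config a \linkS4class{DetectorConfig}.
#' @return a single intensity value.
#' @export
computeThreshold <- function(segment, config = DetectorConfig()) {
  stopifnot(is(segment, "MosaicImage"), is(config, "DetectorConfig"))
  if (config@thresholdMode == "manual") {
    if (!is.finite(config@manualThreshold))
      stop("manual threshold mode needs a finite manualThreshold")
    return(config@manualThreshold)
  }
  otsuThreshold(pixels(segment))
}

#' Binarize a segment
#'
#' Foreground is strictly above the threshold; optional hole filling closes
#' enclosed background (dim nuclear centers) inside somata.
#'
#' @param segment a \linkS4class{MosaicImage}.
#' @param threshold intensity cutoff.
#' @param fillHoles fill enclosed background regions.
#' @return a logical matrix of the segment's shape.
#' @export
binarizeSegment <- function(segment, threshold, fillHoles = TRUE) {
  stopifnot(is(segment, "MosaicImage"))
  mask <- pixels(segment) > threshold
  if (fillHoles && any(mask) && !all(mask))
    mask <- fillHull(mask * 1L) > 0L
  mask
}

#' Label connected foreground components
#'
#' Components are maximal connected sets of foreground pixels under the
#' configured neighborhood (8-connectivity by default: round somata rarely
#' touch only diagonally by accident). Each component's outer contour is
#' traced so boundaries can be drawn on overlays.
#'
#' @param mask logical matrix from \code{\link{binarizeSegment}}.
#' @param config a \linkS4class{DetectorConfig} (only \code{connectivity} is
#'   used).
#' @param pixelSize micrometres per pixel, used to convert pixel areas to
#'   um^2.
#' @param trace trace object boundaries (slightly slower; switch off when
#'   only counts are needed).
#' @return list with \code{labels} (integer matrix, 0 = background),
#'   \code{objects} (data frame: objectId, areaPx, areaUm2, centroidX,
#'   centroidY) and \code{boundaries} (list of ordered (x, y) outlines, empty
#'   when \code{trace = FALSE}).
#' @export
labelObjects <- function(mask, config = DetectorConfig(), pixelSize = 1,
                         trace = TRUE) {
  stopifnot(is.matrix(mask))
  lab <- labelMask(mask, config@connectivity)
  obj <- componentStats(lab, pixelSize)
  bnd <- if (trace && nrow(obj))
    lapply(obj$objectId, function(id) traceBoundary(lab, id))
  else list()
  list(labels = lab, objects = obj, boundaries = bnd)
}

#' Estimate the mean single-cell area
#'
#' The average soma area that the cluster-splitting rule divides by. Robust
#' fixed-point scheme: initialize with the median area of all objects above
#' the size-exclusion cutoff, keep the objects no larger than
#' \code{clusterFactor} times the current estimate (the putative singles),
#' re-estimate as their interquartile-trimmed mean, and iterate (at most 10
#' rounds, stopping at the first repeated membership). Clusters therefore do
#' not inflate the average.
#'
#' @param objects the object data frame from \code{\link{labelObjects}}, or
#'   a numeric vector of areas in um^2.
#' @param config a \linkS4class{DetectorConfig}.
#' @return mean single-cell area in um^2.
#' @export
estimateMeanSingleArea <- function(objects, config = DetectorConfig()) {
  areas <- if (is.data.frame(objects)) objects$areaUm2 else as.numeric(objects)
  cand <- areas[areas > config@minObjectArea]
  if (!length(cand))
    stop("no object above minObjectArea; cannot estimate the single-cell area")
  m <- median(cand)
  member <- rep(NA, length(cand))
  for (it in seq_len(10L)) {
    newMember <- cand <= config@clusterFactor * m
    if (!any(newMember)) break
    mNew <- mean(cand[newMember], trim = 0.25)
    if (identical(newMember, member)) break
    member <- newMember
    m <- mNew
  }
  m
}

#' Classify labeled objects and split clusters
#'
#' The size-segmentation rule at the heart of the counter: objects at or
#' below \code{minObjectArea} are staining noise (0 cells); objects up to
#' \code{clusterFactor} times the mean single-cell area are single cells;
#' anything larger is a cluster of overlapping cells contributing the
#' rounded ratio of its area to the mean single-cell area (half rounds up,
#' floored at 2 -- an identified cluster cannot contribute fewer than two
#' cells).
#'
#' @param objects object data frame from \code{\link{labelObjects}}.
#' @param meanSingleArea mean single-cell area in um^2, > 0.
#' @param config a \linkS4class{DetectorConfig}.
#' @return data frame with \code{objectId}, \code{label}
#'   (noise/single/cluster) and \code{estimatedCells}.
#' @examples
#' obj <- data.frame(objectId = 1:4, areaUm2 = c(10, 66, 120, 205))
#' classifyObjects(obj, meanSingleArea = 60)  # noise, single, 2, 3
#' @export
classifyObjects <- function(objects, meanSingleArea,
                            config = DetectorConfig()) {
  if (!is.finite(meanSingleArea) || meanSingleArea <= 0)
    stop("meanSingleArea must be positive")
  a <- objects$areaUm2
  label <- ifelse(a <= config@minObjectArea, "noise",
                  ifelse(a <= config@clusterFactor * meanSingleArea,
                         "single", "cluster"))
  cells <- integer(length(a))
  cells[label == "single"] <- 1L
  cl <- label == "cluster"
  cells[cl] <- pmax(2L, as.integer(roundHalfUp(a[cl] / meanSingleArea)))
  data.frame(objectId = objects$objectId, label = label,
             estimatedCells = cells, stringsAsFactors = FALSE)
}

#' Count the cells in one segment
#'
#' The full size-segmentation pipeline: filter, threshold, binarize, label,
#' exclude noise by size, estimate the mean single-cell area, split clusters
#' by rounded area ratio, and total the cells. Entirely deterministic: the
#' same segment and configuration always give a bit-identical result. A
#' segment in which nothing survives size exclusion yields a zero count (a
#' constant segment under automatic thresholding is an error instead, to
#' surface acquisition failures).
#'
#' @param segment a calibrated \linkS4class{MosaicImage}.
#' @param config a \linkS4class{DetectorConfig}.
#' @param trace trace object boundaries for overlays.
#' @return a \linkS4class{SegmentCount}.
#' @examples
#' spec <- SyntheticSpec(density = 1500, cellRadiusCV = 0,
#'                       overlapPairFraction = 0, noiseSd = 2, seed = 7)
#' scene <- generateSegment(spec)
#' sc <- countSegment(scene$image)
#' nTotalCells(sc) == trueCount(scene$truth)
#' @export
countSegment <- function(segment, config = DetectorConfig(), trace = TRUE) {
  stopifnot(is(segment, "MosaicImage"), is(config, "DetectorConfig"))
  validObject(config)
  pre <- preprocessSegment(segment, config)
  thr <- computeThreshold(pre, config)
  mask <- binarizeSegment(pre, thr, config@fillHoles)
  lo <- labelObjects(mask, config, pixelSize(segment), trace = trace)
  obj <- lo$objects
  if (nrow(obj) == 0L || !any(obj$areaUm2 > config@minObjectArea)) {
    objects <- cbind(obj, data.frame(label = character(nrow(obj)),
                                     estimatedCells = integer(nrow(obj))))
    if (nrow(objects)) {
      objects$label <- "noise"
      objects$estimatedCells <- 0L
    }
    return(new("SegmentCount", objects = objects, boundaries = lo$boundaries,
               meanSingleArea = NA_real_, nSingles = 0L,
               nClusterObjects = 0L, nTotalCells = 0L,
               thresholdUsed = as.numeric(thr),
               pixelSize = pixelSize(segment)))
  }
  m <- estimateMeanSingleArea(obj, config)
  cls <- classifyObjects(obj, m, config)
  objects <- cbind(obj, cls[, c("label", "estimatedCells")])
  nS <- sum(objects$label == "single")
  nC <- sum(objects$label == "cluster")
  tot <- nS + sum(objects$estimatedCells[objects$label == "cluster"])
  new("SegmentCount", objects = objects, boundaries = lo$boundaries,
      meanSingleArea = m, nSingles = as.integer(nS),
      nClusterObjects = as.integer(nC), nTotalCells = as.integer(tot),
      thresholdUsed = as.numeric(thr), pixelSize = pixelSize(segment))
}

#' Render an annotated overlay of a counted segment
#'
#' Echoes the annotation semantics of the interactive tool: red contours
#' around detected boundaries, red marks on single cells, green on
#' size-excluded noise, blue on overlapping-cell clusters.
#'
#' @param segment the counted \linkS4class{MosaicImage}.
#' @param count the matching \linkS4class{SegmentCount} (counted with
#'   \code{trace = TRUE}).
#' @return an height x width x 3 RGB array in [0, 1], writable with
#'   \code{tiff::writeTIFF}.
#' @export
overlayImage <- function(segment, count) {
  stopifnot(is(segment, "MosaicImage"), is(count, "SegmentCount"))
  p <- pixels(segment)
  g <- p / max(p, 1)
  rgb <- array(rep(g, 3L), dim = c(dim(p), 3L))
  o <- count@objects
  mark <- function(x, y, ch) {
    x <- as.integer(roundHalfUp(x)); y <- as.integer(roundHalfUp(y))
    xs <- pmax(1L, pmin(ncol(p), (x - 1L):(x + 1L)))
    ys <- pmax(1L, pmin(nrow(p), (y - 1L):(y + 1L)))
    for (c3 in 1:3) rgb[ys, xs, c3] <<- as.numeric(c3 == ch)
  }
  for (b in count@boundaries)
    for (i in seq_len(nrow(b))) {
      rgb[b[i, 2L], b[i, 1L], 1L] <- 1
      rgb[b[i, 2L], b[i, 1L], 2:3] <- 0
    }
  if (nrow(o))
    for (i in seq_len(nrow(o)))
      mark(o$centroidX[i], o$centroidY[i],
           switch(o$label[i], noise = 2L, single = 1L, cluster = 3L))
  rgb
}
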
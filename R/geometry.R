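#' @include AllClasses.R
NULL

#' Define the sampling layout over a flat-mounted retina
#'
#' The analysis is semi-automated: the user marks the optic-nerve-head
#' position, the orientation of the four cut lobes and the outer radius of
#' the tissue; everything downstream is deterministic. Angles are in radians,
#' measured from the +x (column) axis towards the +y (row) axis; the two
#' axes and their opposites cut the mount into four quadrants numbered
#' counterclockwise from the first axis.
#'
#' @param image the \linkS4class{MosaicImage} of the whole mount.
#' @param center (x, y) optic-nerve-head position in pixels; must lie inside
#'   the image.
#' @param outerRadius distance from the center to the retinal edge in
#'   micrometres.
#' @param quadrantAxes two cut-axis angles in radians (default 0 and pi/2,
#'   i.e. upright cuts).
#' @return a \linkS4class{RetinaLayout}.
#' @examples
#' img <- blankMosaic(400, 400, pixelSize = 2)
#' buildLayout(img, center = c(200, 200), outerRadius = 380)
#' @export
buildLayout <- function(image, center, outerRadius, quadrantAxes = c(0, pi / 2)) {
  stopifnot(is(image, "MosaicImage"))
  if (!is.numeric(outerRadius) || length(outerRadius) != 1L ||
      !is.finite(outerRadius) || outerRadius <= 0)
    stop("outerRadius must be a single positive length in um")
  new("RetinaLayout", center = as.numeric(center),
      quadrantAxes = as.numeric(quadrantAxes),
      outerRadius = as.numeric(outerRadius), pixelSize = pixelSize(image),
      imageDim = dim(image))
}

#' Blank calibrated canvas
#'
#' Convenience constructor used to lay out synthetic whole mounts.
#'
#' @param nrow,ncol canvas size in pixels.
#' @param pixelSize micrometres per pixel.
#' @param value fill intensity.
#' @return a \linkS4class{MosaicImage}.
#' @export
blankMosaic <- function(nrow, ncol, pixelSize, value = 0) {
  MosaicImage(matrix(value, nrow, ncol), pixelSize)
}

## sector boundary angles (length 5, last = first + 2*pi) of a layout
.sectorBounds <- function(layout) {
  a <- layout@quadrantAxes %% (2 * pi)
  b <- sort(unique(c(a, (a + pi) %% (2 * pi))))
  c(b, b[1L] + 2 * pi)
}

#' Place the twelve analysis segments
#'
#' One square segment per (quadrant, eccentricity band). Each segment is
#' centered on its quadrant's bisector at the band's mid-radius
#' (\code{bandFractions} times the outer radius) and is axis-aligned, so its
#' pixels are copied verbatim with no resampling.
#'
#' @param layout a \linkS4class{RetinaLayout}.
#' @param sideUm segment edge length in micrometres (350 by default, the
#'   size used throughout the counting workflow).
#' @param bandFractions three strictly increasing fractions in (0, 1]; the
#'   central, middle and peripheral segments sit at these fractions of the
#'   outer radius.
#' @return a list of 12 \linkS4class{SegmentROI} objects named
#'   \code{"Q<q>.<eccentricity>"}.
#' @examples
#' img <- blankMosaic(2200, 2200, pixelSize = 2)
#' rois <- sampleRegions(buildLayout(img, c(1100, 1100), 2000))
#' length(rois)  # 12
#' @export
sampleRegions <- function(layout, sideUm = 350,
                          bandFractions = c(0.25, 0.55, 0.85)) {
  stopifnot(is(layout, "RetinaLayout"))
  if (length(bandFractions) != 3L || any(!is.finite(bandFractions)) ||
      any(diff(bandFractions) <= 0) || bandFractions[1L] <= 0 ||
      bandFractions[3L] > 1)
    stop("bandFractions must be three strictly increasing fractions in (0, 1]")
  if (sideUm <= 0) stop("sideUm must be > 0")
  ps <- layout@pixelSize
  sidePx <- as.integer(roundHalfUp(sideUm / ps))
  b <- .sectorBounds(layout)
  rois <- vector("list", 12L)
  labels <- character(12L)
  i <- 0L
  for (q in 1:4) {
    theta <- (b[q] + b[q + 1L]) / 2
    for (k in 1:3) {
      rUm <- bandFractions[k] * layout@outerRadius
      cx <- layout@center[1L] + rUm / ps * cos(theta)
      cy <- layout@center[2L] + rUm / ps * sin(theta)
      ox <- as.integer(roundHalfUp(cx - (sidePx - 1) / 2))
      oy <- as.integer(roundHalfUp(cy - (sidePx - 1) / 2))
      if (ox < 1L || oy < 1L || ox + sidePx - 1L > layout@imageDim[2L] ||
          oy + sidePx - 1L > layout@imageDim[1L])
        stop(sprintf(
          "segment Q%d/%s falls outside the image; increase the canvas or reduce sideUm",
          q, .eccLevels[k]))
      i <- i + 1L
      rois[[i]] <- new("SegmentROI", quadrant = q,
                       eccentricity = .eccLevels[k],
                       origin = c(ox, oy), sidePx = sidePx,
                       sideUm = as.numeric(sideUm), pixelSize = ps)
      labels[i] <- sprintf("Q%d.%s", q, .eccLevels[k])
    }
  }
  ## the twelve segments must not overlap (they sample independent regions)
  for (a in seq_len(11L)) for (bb in (a + 1L):12L) {
    oa <- rois[[a]]@origin; ob <- rois[[bb]]@origin
    if (abs(oa[1L] - ob[1L]) < sidePx && abs(oa[2L] - ob[2L]) < sidePx)
      stop("segments overlap; the outer radius is too small for this segment size")
  }
  names(rois) <- labels
  rois
}

#' Tabulate a list of segment ROIs
#'
#' @param rois list of \linkS4class{SegmentROI} as returned by
#'   \code{\link{sampleRegions}}.
#' @return data frame with pixel coordinates of each segment, suitable for
#'   CSV export.
#' @export
roiTable <- function(rois) {
  do.call(rbind, lapply(rois, function(r)
    data.frame(quadrant = r@quadrant, eccentricity = r@eccentricity,
               origin_x = r@origin[1L], origin_y = r@origin[2L],
               side_px = r@sidePx, side_um = r@sideUm)))
}

#' Extract one analysis segment from a mosaic
#'
#' Pixels are copied verbatim (no interpolation); calibration is inherited.
#'
#' @param image a \linkS4class{MosaicImage}.
#' @param roi a \linkS4class{SegmentROI} lying fully inside the image.
#' @return a \linkS4class{MosaicImage} of \code{roi@sidePx} pixels per side.
#' @export
extractSegment <- function(image, roi) {
  stopifnot(is(image, "MosaicImage"), is(roi, "SegmentROI"))
  if (abs(pixelSize(image) - roi@pixelSize) > 1e-9)
    stop("ROI and image calibration disagree")
  d <- dim(image)
  ox <- roi@origin[1L]; oy <- roi@origin[2L]; s <- roi@sidePx
  if (ox < 1L || oy < 1L || ox + s - 1L > d[2L] || oy + s - 1L > d[1L])
    stop("ROI exceeds the image bounds")
  MosaicImage(pixels(image)[oy:(oy + s - 1L), ox:(ox + s - 1L)],
              pixelSize(image))
}
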
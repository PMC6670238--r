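#' @include RGCount-package.R
NULL

#' Accessors for image and result objects
#'
#' @param object an object of one of the classes defined in this package.
#' @return \code{pixels} returns the intensity matrix; \code{pixelSize} the
#'   calibration in micrometres per pixel; \code{planes} the list of z-planes;
#'   \code{nTotalCells}, \code{meanSingleArea} and \code{thresholdUsed} the
#'   corresponding slots of a \linkS4class{SegmentCount}; \code{objectTable}
#'   the per-object data frame; \code{trueCount} the number of planted cells
#'   in a \linkS4class{GroundTruth}; \code{meanDensity} and
#'   \code{regionalMeans} the per-retina summaries of a
#'   \linkS4class{RetinaSummary}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))

#' @rdname accessors
#' @export
setGeneric("nTotalCells", function(object) standardGeneric("nTotalCells"))

#' @rdname accessors
#' @export
setGeneric("meanSingleArea", function(object) standardGeneric("meanSingleArea"))

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))

#' @rdname accessors
#' @export
setGeneric("objectTable", function(object) standardGeneric("objectTable"))

#' @rdname accessors
#' @export
setGeneric("trueCount", function(object) standardGeneric("trueCount"))

#' @rdname accessors
#' @export
setGeneric("meanDensity", function(object) standardGeneric("meanDensity"))

#' @rdname accessors
#' @export
setGeneric("regionalMeans", function(object) standardGeneric("regionalMeans"))

#' Project a z-stack onto a single plane
#'
#' @param stack a \linkS4class{ZStack}.
#' @param method \code{"max"} for a maximum-intensity projection (the
#'   default; preserves bright somata across focal planes) or \code{"mean"}.
#' @return a \linkS4class{MosaicImage} with the shape of one plane and the
#'   lateral calibration of the stack.
#' @export
setGeneric("projectStack", function(stack, method = c("max", "mean"))
  standardGeneric("projectStack"))
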
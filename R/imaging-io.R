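#' @include AllClasses.R
NULL

#' Read a calibrated single-channel TIFF
#'
#' Reads an 8- or 16-bit single-channel TIFF with user-supplied pixel
#' calibration. Intensities are returned unmodified (integer sample values,
#' not rescaled). A multi-page file is returned as a \linkS4class{ZStack}
#' for projection with \code{\link{projectStack}}; pixel calibration is
#' always supplied by the caller because TIFF resolution tags vary too much
#' between microscopes to be trusted.
#'
#' @param path path to the TIFF file.
#' @param pixelSize micrometres per pixel (isotropic), > 0.
#' @param zStep axial step in micrometres used when the file is a stack
#'   (default 3, a typical epifluorescence z-step for flat mounts).
#' @return a \linkS4class{MosaicImage}, or a \linkS4class{ZStack} when the
#'   file has several pages.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(matrix(0, 4, 4), tf)
#' readMosaic(tf, pixelSize = 1)
#' @export
readMosaic <- function(path, pixelSize, zStep = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(pixelSize) || length(pixelSize) != 1L ||
      !is.finite(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be a single positive number (um/pixel)")
  pages <- readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- NA_real_
  asPlane <- function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] > 1L)
        stop("multi-channel TIFF: the counting signal is ambiguous; ",
             "export a single channel")
      p <- p[, , 1L]
    }
    matrix(as.numeric(p), nrow(p), ncol(p))   # drop TIFF tag attributes
  }
  planes <- lapply(pages, asPlane)
  if (length(planes) == 1L)
    MosaicImage(planes[[1L]], pixelSize, bitDepth = as.numeric(bits))
  else
    ZStack(planes, zStep = zStep, pixelSize = pixelSize)
}

#' Write an image as TIFF
#'
#' Sample values are scaled by \code{2^bitsPerSample - 1} and clamped to the
#' representable range, so an image read back with \code{\link{readMosaic}}
#' reproduces integer data exactly.
#'
#' @param image a \linkS4class{MosaicImage}.
#' @param path output path.
#' @param bitsPerSample 8 or 16.
#' @return the path, invisibly.
#' @export
writeMosaic <- function(image, path, bitsPerSample = 16L) {
  stopifnot(is(image, "MosaicImage"), bitsPerSample %in% c(8L, 16L))
  maxVal <- 2^bitsPerSample - 1
  p <- pixels(image)
  p <- pmin(pmax(p / maxVal, 0), 1)
  writeTIFF(p, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

#' @describeIn projectStack maximum- or mean-intensity projection; with a
#'   single plane both methods return that plane unchanged.
setMethod("projectStack", "ZStack", function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  pl <- planes(stack)
  out <- pl[[1L]]
  if (length(pl) > 1L) {
    if (method == "max") {
      for (p in pl[-1L]) out <- pmax(out, p)
    } else {
      for (p in pl[-1L]) out <- out + p
      out <- out / length(pl)
    }
  }
  MosaicImage(out, pixelSize(stack))
})

# ---------------------------------------------------------------------------
# tabular formats
# ---------------------------------------------------------------------------

.countTableCols <- c("animal_id", "eye", "group", "timepoint", "quadrant",
                     "eccentricity", "count", "density")

#' Validate a per-segment count table
#'
#' The count table is the package's tabular interchange format: one row per
#' analysis segment with columns \code{animal_id}, \code{eye} (left/right),
#' \code{group} (EAE/CFA/naive), \code{timepoint} (post-immunization day),
#' \code{quadrant} (1-4), \code{eccentricity}
#' (central/middle/peripheral), \code{count} and \code{density} (cells/mm^2).
#'
#' @param table a data frame.
#' @param sideUm segment side length used to check that density and count
#'   agree within rounding.
#' @return the table, invisibly, or an error describing the defect.
#' @export
validateCountTable <- function(table, sideUm = 350) {
  if (!is.data.frame(table)) stop("count table must be a data frame")
  miss <- setdiff(.countTableCols, names(table))
  if (length(miss)) stop("count table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(table)) return(invisible(table))
  if (!all(table$eye %in% .eyeLevels))
    stop("unknown eye label; expected left/right")
  if (!all(table$group %in% .groupLevels))
    stop("unknown group label; expected EAE/CFA/naive")
  if (!all(table$eccentricity %in% .eccLevels))
    stop("unknown eccentricity label; expected central/middle/peripheral")
  if (!all(table$quadrant %in% 1:4)) stop("quadrant must be 1..4")
  if (any(table$count < 0) || any(table$count != floor(table$count)))
    stop("count must be a non-negative integer")
  areaMm2 <- (sideUm / 1000)^2
  if (any(abs(table$density - table$count / areaMm2) > 0.5))
    stop("density and count disagree for the stated segment size")
  key <- paste(table$animal_id, table$eye, table$timepoint, table$quadrant,
               table$eccentricity)
  if (anyDuplicated(key))
    stop("duplicate (animal, eye, timepoint, quadrant, eccentricity) rows")
  invisible(table)
}

#' Read and write count tables
#'
#' Comma-delimited UTF-8 with a fixed header; numeric fields are written with
#' enough digits that a round trip reproduces them exactly.
#'
#' @param table a valid count table (see \code{\link{validateCountTable}}).
#' @param path file path.
#' @param sideUm segment side length for validation.
#' @return \code{readCountTable} returns the validated data frame.
#' @export
writeCountTable <- function(table, path, sideUm = 350) {
  validateCountTable(table, sideUm)
  out <- table[, .countTableCols, drop = FALSE]
  out$density <- formatC(out$density, digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path, sideUm = 350) {
  if (!file.exists(path)) stop("file not found: ", path)
  t <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(animal_id = "character", eye = "character",
                               group = "character", eccentricity = "character"),
                fileEncoding = "UTF-8")
  t$timepoint <- as.integer(t$timepoint)
  t$quadrant <- as.integer(t$quadrant)
  t$count <- as.integer(t$count)
  t$density <- as.numeric(t$density)
  validateCountTable(t, sideUm)
  t
}

#' Empty count table
#'
#' @return a zero-row data frame with the count-table schema.
#' @export
emptyCountTable <- function() {
  data.frame(animal_id = character(0), eye = character(0),
             group = character(0), timepoint = integer(0),
             quadrant = integer(0), eccentricity = character(0),
             count = integer(0), density = numeric(0),
             stringsAsFactors = FALSE)
}

.animalCols <- c("animal_id", "group", "peak_behavior_score", "sex")

#' Validate, read and write per-animal records
#'
#' One row per animal: \code{animal_id}, \code{group} (EAE/CFA/naive),
#' \code{peak_behavior_score} (the 0-5 EAE severity scale in 0.5 steps) and
#' an optional \code{sex}.
#'
#' @param records a data frame.
#' @param path file path.
#' @return \code{readAnimalRecords} returns the validated data frame.
#' @export
validateAnimalRecords <- function(records) {
  if (!is.data.frame(records)) stop("animal records must be a data frame")
  need <- setdiff(.animalCols, "sex")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("animal records missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(records)) return(invisible(records))
  if (!all(records$group %in% .groupLevels))
    stop("unknown group label; expected EAE/CFA/naive")
  s <- records$peak_behavior_score
  if (any(!is.finite(s)) || any(s < 0) || any(s > 5) ||
      any(abs(s * 2 - round(s * 2)) > 1e-9))
    stop("peak_behavior_score must lie in [0, 5] in 0.5 steps")
  if (anyDuplicated(records$animal_id)) stop("duplicate animal_id")
  invisible(records)
}

#' @rdname validateAnimalRecords
#' @export
writeAnimalRecords <- function(records, path) {
  validateAnimalRecords(records)
  if (is.null(records$sex)) records$sex <- NA_character_
  write.csv(records[, .animalCols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname validateAnimalRecords
#' @export
readAnimalRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(animal_id = "character", group = "character"),
                fileEncoding = "UTF-8")
  r$peak_behavior_score <- as.numeric(r$peak_behavior_score)
  validateAnimalRecords(r)
  r
}

#' Write the ground truth of a synthetic segment as CSV
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  df <- data.frame(x_um = truth@centers[, 1L], y_um = truth@centers[, 2L],
                   radius_um = truth@radii, pair_id = truth@pairId)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
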
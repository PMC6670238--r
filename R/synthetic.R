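#' @include AllClasses.R
NULL

## smooth radial soma profile: 1 in the core, 0.5 at d = r, ~0 beyond 1.3 r.
## The half-maximum convention means a mid-contrast threshold recovers discs
## of the planted radii; the steep (but smooth, multi-pixel) shoulder keeps
## the halo short so neighboring somata do not fuse through their tails.
.somaProfile <- function(d2, r) exp(-log(2) * (d2 / r^2)^5)

## place n points uniformly in [lo, hi]^2 with a hard minimum separation
## from the rows of `existing`; dart throwing with a retry cap.
.throwDart <- function(existing, nExisting, lo, hi, minSep, tries = 5000L) {
  for (t in seq_len(tries)) {
    p <- runif(2L, lo, hi)
    if (nExisting == 0L) return(p)
    d2 <- (existing[seq_len(nExisting), 1L] - p[1L])^2 +
          (existing[seq_len(nExisting), 2L] - p[2L])^2
    if (min(d2) >= minSep^2) return(p)
  }
  stop("requested density is infeasible under minSeparation (retry cap exceeded)")
}

#' Generate a synthetic segment with known ground truth
#'
#' Renders bright, roughly circular somata (smooth radial falloff, half
#' maximum at the planted radius) over a noisy background. The planted count
#' is deterministic -- \code{round(density * area)} -- so exact-recovery
#' tests are sharp. A configurable fraction of cells is placed as touching
#' pairs at a center distance of 1.2 soma radii (merged area about 1.7-2
#' single areas, the regime the cluster-splitting rule addresses); all other
#' cells respect the minimum separation. Cells are kept clear of the segment
#' border so every planted cell is fully visible. The seed fixes the whole
#' scene: identical specs give bit-identical images and truth.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{image} (a \linkS4class{MosaicImage}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' scene <- generateSegment(SyntheticSpec(density = 3683, seed = 1))
#' trueCount(scene$truth)  # round(3683 * 0.1225) = 451
#' @export
generateSegment <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  ps <- spec@pixelSize
  side <- spec@sideUm
  sidePx <- as.integer(roundHalfUp(side / ps))
  n <- as.integer(roundHalfUp(spec@density * (side / 1000)^2))
  withSeed(spec@seed, {
    rbar <- spec@cellRadiusMean
    radii <- if (n > 0L)
      pmax(0.2 * rbar, rnorm(n, rbar, spec@cellRadiusCV * rbar))
    else numeric(0)
    nPairCells <- 2L * (as.integer(roundHalfUp(spec@overlapPairFraction * n)) %/% 2L)
    nPairs <- nPairCells %/% 2L
    margin <- if (n > 0L) max(radii) + 0.6 * rbar + 1 else 1
    lo <- margin; hi <- side - margin
    if (n > 0L && hi <= lo)
      stop("segment too small for the cell size")
    centers <- matrix(NA_real_, max(n, 1L), 2L)
    pairId <- rep(NA_integer_, n)
    placed <- 0L
    i <- 1L
    for (p in seq_len(nPairs)) {
      r1 <- radii[i]; r2 <- radii[i + 1L]
      d <- 1.2 * (r1 + r2) / 2
      ok <- FALSE
      for (t in seq_len(5000L)) {
        mid <- runif(2L, lo, hi)
        th <- runif(1L, 0, 2 * pi)
        u <- c(cos(th), sin(th)) * d / 2
        c1 <- mid + u; c2 <- mid - u
        if (any(c(c1, c2) < margin) || any(c(c1, c2) > side - margin)) next
        if (placed > 0L) {
          ex <- centers[seq_len(placed), , drop = FALSE]
          d2 <- pmin((ex[, 1L] - c1[1L])^2 + (ex[, 2L] - c1[2L])^2,
                     (ex[, 1L] - c2[1L])^2 + (ex[, 2L] - c2[2L])^2)
          if (min(d2) < spec@minSeparation^2) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop("requested density is infeasible under minSeparation (retry cap exceeded)")
      centers[i, ] <- c1
      centers[i + 1L, ] <- c2
      pairId[i] <- pairId[i + 1L] <- p
      placed <- placed + 2L
      i <- i + 2L
    }
    while (i <= n) {
      centers[i, ] <- .throwDart(centers, placed, lo, hi, spec@minSeparation)
      placed <- placed + 1L
      i <- i + 1L
    }
    ## render
    img <- matrix(0, sidePx, sidePx)
    for (k in seq_len(n)) {
      r <- radii[k]
      ext <- 1.6 * r
      cxs <- max(1L, floor((centers[k, 1L] - ext) / ps)) :
             min(sidePx, ceiling((centers[k, 1L] + ext) / ps))
      cys <- max(1L, floor((centers[k, 2L] - ext) / ps)) :
             min(sidePx, ceiling((centers[k, 2L] + ext) / ps))
      xs <- (cxs - 0.5) * ps - centers[k, 1L]
      ys <- (cys - 0.5) * ps - centers[k, 2L]
      d2 <- outer(ys^2, xs^2, "+")
      img[cys, cxs] <- img[cys, cxs] + .somaProfile(d2, r)
    }
    img <- spec@backgroundLevel +
      (spec@cellIntensity - spec@backgroundLevel) * pmin(img, 1)
    if (spec@noiseSd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec@noiseSd), sidePx, sidePx)
    img[img < 0] <- 0
    truth <- new("GroundTruth",
                 centers = if (n > 0L) centers[seq_len(n), , drop = FALSE]
                           else matrix(numeric(0), 0L, 2L),
                 radii = radii, pairId = pairId, sideUm = side)
    list(image = MosaicImage(img, ps), truth = truth)
  })
}

#' Generate a synthetic whole mount with a planted eccentricity gradient
#'
#' Builds a calibrated canvas matching a \linkS4class{RetinaLayout}, plants
#' cells inside each of the twelve standard sampling segments at the density
#' of its eccentricity band (real retinas show central > middle >
#' peripheral), and returns the image together with a ground-truth count
#' table keyed like the detector's output. Tissue outside the sampled
#' segments is plain noisy background.
#'
#' @param layout a \linkS4class{RetinaLayout}; its pixel size must match the
#'   spec's.
#' @param densities named numeric: planted cells/mm^2 for \code{central},
#'   \code{middle} and \code{peripheral}.
#' @param spec a \linkS4class{SyntheticSpec} providing cell appearance (its
#'   own density and seed are ignored).
#' @param seed integer fixing the whole mount.
#' @param animalId,eye,group,timepoint identifiers for the truth table.
#' @param bandFractions passed to \code{\link{sampleRegions}}.
#' @return list with \code{image}, \code{truth} (count table data frame) and
#'   \code{rois}.
#' @export
generateRetina <- function(layout, densities, spec = SyntheticSpec(0),
                           seed = 1L, animalId = "sim", eye = "left",
                           group = "naive", timepoint = 42L,
                           bandFractions = c(0.25, 0.55, 0.85)) {
  stopifnot(is(layout, "RetinaLayout"), is(spec, "SyntheticSpec"))
  if (!all(.eccLevels %in% names(densities)))
    stop("densities must be named central/middle/peripheral")
  if (any(densities < 0)) stop("densities must be >= 0")
  if (abs(layout@pixelSize - spec@pixelSize) > 1e-9)
    stop("layout and spec pixel sizes disagree")
  rois <- sampleRegions(layout, spec@sideUm, bandFractions)
  withSeed(seed, {
    subseeds <- sample.int(.Machine$integer.max, 12L)
    canvas <- matrix(spec@backgroundLevel, layout@imageDim[1L],
                     layout@imageDim[2L])
    if (spec@noiseSd > 0)
      canvas <- canvas + matrix(rnorm(length(canvas), 0, spec@noiseSd),
                                nrow(canvas), ncol(canvas))
    canvas[canvas < 0] <- 0
    rows <- vector("list", 12L)
    for (i in seq_along(rois)) {
      roi <- rois[[i]]
      si <- spec
      si@density <- as.numeric(densities[[roi@eccentricity]])
      si@seed <- subseeds[i]
      scene <- generateSegment(si)
      ox <- roi@origin[1L]; oy <- roi@origin[2L]; s <- roi@sidePx
      canvas[oy:(oy + s - 1L), ox:(ox + s - 1L)] <- pixels(scene$image)
      cnt <- trueCount(scene$truth)
      rows[[i]] <- data.frame(
        animal_id = animalId, eye = eye, group = group,
        timepoint = as.integer(timepoint), quadrant = roi@quadrant,
        eccentricity = roi@eccentricity, count = cnt,
        density = cnt / (spec@sideUm / 1000)^2, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    validateCountTable(truth, spec@sideUm)
    list(image = MosaicImage(canvas, spec@pixelSize), truth = truth,
         rois = rois)
  })
}

#' Generate a synthetic animal cohort
#'
#' Per-animal planted mean densities are drawn from group distributions and
#' behavior scores from a decreasing function of planted density plus noise,
#' clamped to the 0-5 clinical scale and snapped to its 0.5 steps. With zero
#' score noise the planted density/score relation is strictly monotone, so a
#' rank correlation of -1 is the expected recovery. Group sizes and
#' between-animal spreads default to the study design this package models:
#' 11 diseased (EAE) vs 8 adjuvant-control (CFA) animals with SEM-derived
#' spreads.
#'
#' @param nPerGroup named integer vector of animals per group.
#' @param groupDensityMeans named numeric, planted mean density per group in
#'   cells/mm^2.
#' @param betweenAnimalSd between-animal SD per group (recycled).
#' @param scoreModel monotone decreasing function density -> score.
#' @param scoreNoiseSd SD of the additive score noise before snapping.
#' @param seed integer.
#' @return list with \code{animals} (animal_id, group, planted_density) and
#'   \code{records} (a valid animal-record table with peak behavior scores).
#' @export
generateCohort <- function(nPerGroup = c(EAE = 11L, CFA = 8L),
                           groupDensityMeans = c(EAE = 2272, CFA = 3683),
                           betweenAnimalSd = c(EAE = 484, CFA = 359),
                           scoreModel = function(d) 5 * (4000 - d) / 2500,
                           scoreNoiseSd = 0.5, seed = 1L) {
  if (any(betweenAnimalSd < 0) || scoreNoiseSd < 0)
    stop("standard deviations must be >= 0")
  if (is.null(names(nPerGroup)) ||
      !all(names(nPerGroup) %in% names(groupDensityMeans)))
    stop("nPerGroup and groupDensityMeans must share group names")
  sds <- rep_len(betweenAnimalSd, length(nPerGroup))
  names(sds) <- names(nPerGroup)
  if (!is.null(names(betweenAnimalSd)) &&
      all(names(nPerGroup) %in% names(betweenAnimalSd)))
    sds <- betweenAnimalSd[names(nPerGroup)]
  withSeed(seed, {
    rows <- list()
    for (g in names(nPerGroup)) {
      for (i in seq_len(nPerGroup[[g]])) {
        d <- max(1, rnorm(1L, groupDensityMeans[[g]], sds[[g]]))
        s <- scoreModel(d) + if (scoreNoiseSd > 0) rnorm(1L, 0, scoreNoiseSd) else 0
        s <- min(5, max(0, roundHalfUp(s * 2) / 2))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s%02d", g, i), group = g,
          planted_density = d, peak_behavior_score = s,
          stringsAsFactors = FALSE)
      }
    }
    animals <- do.call(rbind, rows)
    records <- data.frame(animal_id = animals$animal_id,
                          group = animals$group,
                          peak_behavior_score = animals$peak_behavior_score,
                          sex = NA_character_, stringsAsFactors = FALSE)
    validateAnimalRecords(records)
    list(animals = animals, records = records)
  })
}
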
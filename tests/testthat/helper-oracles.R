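# Shared fixtures and independent oracles, all built in code.

## Brute-force flood-fill labeling, independent of the package's run-length
## implementation; used as the connected-components oracle.
bfsLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          r <- p[1L] + offs[k, 1L]; c <- p[2L] + offs[k, 2L]
          if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

## label matrices describe the same partition of foreground pixels?
samePartition <- function(a, b) {
  fa <- split(which(a > 0L), a[a > 0L])
  fb <- split(which(b > 0L), b[b > 0L])
  setequal(lapply(fa, sort), lapply(fb, sort))
}

## a "clean" scene: uniform-size, well-separated cells, low noise (2% of the
## 140-unit contrast), no planted pairs -- the regime where counting must be
## exact.
cleanSpec <- function(seed, density = 1600)
  SyntheticSpec(density = density, cellRadiusCV = 0, overlapPairFraction = 0,
                noiseSd = 2.8, minSeparation = 14, seed = seed)

## rectangle-archetype scene: disjoint axis-aligned rectangles of known pixel
## areas at 1 um/px, bright on dark, so thresholding and labeling recover the
## analytic areas exactly. Returns the image plus the analytic areas.
archetypeScene <- function(widths, heights, dim = 300L, gap = 4L) {
  stopifnot(length(widths) == length(heights))
  img <- matrix(10, dim, dim)
  x <- gap + 1L; y <- gap + 1L; rowH <- 0L
  for (k in seq_along(widths)) {
    w <- widths[k]; h <- heights[k]
    if (x + w + gap > dim) { x <- gap + 1L; y <- y + rowH + gap; rowH <- 0L }
    stopifnot(y + h + gap <= dim)
    img[y:(y + h - 1L), x:(x + w - 1L)] <- 200
    x <- x + w + gap
    rowH <- max(rowH, h)
  }
  list(image = MosaicImage(img, pixelSize = 1),
       areas = as.numeric(widths * heights))
}

## analytic size-segmentation count: the classification arithmetic applied
## to known areas, independent of any image processing.
analyticCount <- function(areas, meanSingleArea, config = DetectorConfig()) {
  a <- areas[areas > config@minObjectArea]
  singles <- a[a <= config@clusterFactor * meanSingleArea]
  clusters <- a[a > config@clusterFactor * meanSingleArea]
  length(singles) + sum(pmax(2, floor(clusters / meanSingleArea + 0.5)))
}

## detector configuration for archetype scenes: no filtering, fixed
## threshold between background (10) and foreground (200)
archetypeConfig <- function() DetectorConfig(smoothingRadius = 0,
                                             thresholdMode = "manual",
                                             manualThreshold = 100,
                                             fillHoles = FALSE)

## a valid 12-row count table for one retina
makeCountTable <- function(counts, animal = "m1", eye = "left",
                           group = "naive", timepoint = 42L, sideUm = 350) {
  grid <- expand.grid(quadrant = 1:4,
                      eccentricity = c("central", "middle", "peripheral"),
                      stringsAsFactors = FALSE)
  data.frame(animal_id = animal, eye = eye, group = group,
             timepoint = as.integer(timepoint), quadrant = grid$quadrant,
             eccentricity = grid$eccentricity, count = as.integer(counts),
             density = counts / (sideUm / 1000)^2, stringsAsFactors = FALSE)
}
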
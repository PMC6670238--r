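# The size-segmentation detector, stage by stage and end to end.

test_that("preprocessing is the identity at radius zero and smooths otherwise", {
  set.seed(2)
  img <- MosaicImage(matrix(runif(400, 0, 255), 20, 20), 1)
  cfg0 <- DetectorConfig(smoothingRadius = 0)
  expect_identical(pixels(preprocessSegment(img, cfg0)), pixels(img))

  const <- MosaicImage(matrix(80, 20, 20), 1)
  sm <- preprocessSegment(const, DetectorConfig(smoothingRadius = 2))
  expect_equal(pixels(sm), pixels(const), tolerance = 1e-6)

  peak <- matrix(0, 21, 21); peak[11, 11] <- 100
  out <- preprocessSegment(MosaicImage(peak, 1), DetectorConfig(smoothingRadius = 1))
  expect_lt(max(pixels(out)), 100)
})

test_that("thresholding: manual passes through, Otsu separates a bimodal image", {
  img <- MosaicImage(matrix(50, 5, 5), 1)
  cfg <- DetectorConfig(thresholdMode = "manual", manualThreshold = 117)
  expect_identical(computeThreshold(img, cfg), 117)

  ## two-valued image: 90% at 10, 10% at 200
  v <- c(rep(10, 90), rep(200, 10))
  two <- MosaicImage(matrix(v, 10, 10), 1)
  thr <- computeThreshold(two, DetectorConfig())
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(sum(binarizeSegment(two, thr)), 10L)

  expect_error(computeThreshold(img, DetectorConfig()), "constant")
})

test_that("the Otsu threshold agrees with an independent implementation", {
  set.seed(7)
  v <- c(rnorm(600, 40, 8), rnorm(400, 150, 20))
  v <- pmax(v, 0)
  img <- MosaicImage(matrix(v, 25, 40), 1)
  mine <- computeThreshold(img, DetectorConfig())
  p <- pixels(img)
  ref <- EBImage::otsu(p / max(p), range = range(p / max(p)), levels = 256) * max(p)
  ## same binarization even if the representative value inside the optimal
  ## histogram gap differs
  expect_identical(p > mine, p > ref)
})

test_that("automatic thresholding is invariant to intensity gain", {
  scene <- generateSegment(cleanSpec(3, density = 800))
  img <- scene$image
  img3 <- MosaicImage(pixels(img) * 3.7, pixelSize(img))
  c1 <- countSegment(img, trace = FALSE)
  c3 <- countSegment(img3, trace = FALSE)
  expect_identical(nTotalCells(c1), nTotalCells(c3))
  expect_identical(objectTable(c1)$areaPx, objectTable(c3)$areaPx)
})

test_that("binarization edge cases behave as defined", {
  img <- MosaicImage(matrix(c(0, 255), 8, 8), 1)
  expect_false(any(binarizeSegment(img, 255)))
  expect_true(all(binarizeSegment(img, -1)))
  chk <- matrix(0, 8, 8); chk[(row(chk) + col(chk)) %% 2 == 0] <- 255
  m <- binarizeSegment(MosaicImage(chk, 1), 100, fillHoles = FALSE)
  expect_identical(m, chk == 255)
  ## hole filling closes an enclosed background region
  ring <- matrix(0, 15, 15)
  ring[5:11, 5:11] <- 200; ring[7:9, 7:9] <- 0
  filled <- binarizeSegment(MosaicImage(ring, 1), 100, fillHoles = TRUE)
  expect_identical(sum(filled), 49L)
})

test_that("component labeling matches a flood-fill oracle for 4- and 8-connectivity", {
  ## canonical cases
  two <- matrix(FALSE, 10, 10)
  two[2:4, 2:4] <- TRUE; two[7:9, 6:8] <- TRUE
  lo <- labelObjects(two, DetectorConfig(), pixelSize = 1, trace = FALSE)
  expect_identical(nrow(lo$objects), 2L)
  expect_true(all(lo$objects$areaPx == 9L))

  diagonal <- matrix(FALSE, 4, 4)
  diagonal[1, 1] <- diagonal[2, 2] <- TRUE
  n8 <- nrow(labelObjects(diagonal, DetectorConfig(connectivity = 8L), 1,
                          trace = FALSE)$objects)
  n4 <- nrow(labelObjects(diagonal, DetectorConfig(connectivity = 4L), 1,
                          trace = FALSE)$objects)
  expect_identical(c(n8, n4), c(1L, 2L))

  full <- matrix(TRUE, 6, 7)
  lo <- labelObjects(full, DetectorConfig(), 1, trace = FALSE)
  expect_identical(lo$objects$areaPx, 42L)

  ## random masks against the oracle
  set.seed(11)
  for (i in 1:8) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    for (conn in c(4L, 8L)) {
      mine <- labelObjects(m, DetectorConfig(connectivity = conn), 1,
                           trace = FALSE)$labels
      expect_true(samePartition(mine, bfsLabel(m, conn)),
                  info = sprintf("trial %d conn %d", i, conn))
    }
  }
})

test_that("areas scale with calibration and boundaries outline their objects", {
  m <- matrix(FALSE, 20, 20)
  m[5:10, 5:10] <- TRUE     # 6x6 square
  lo <- labelObjects(m, DetectorConfig(), pixelSize = 0.5)
  expect_identical(lo$objects$areaPx, 36L)
  expect_identical(lo$objects$areaUm2, 9)          # 36 * 0.25
  expect_equal(lo$objects$centroidX, 7.5)
  b <- lo$boundaries[[1L]]
  ## boundary pixels belong to the object and cover its 4-edge pixels
  expect_true(all(m[cbind(b[, "y"], b[, "x"])]))
  edge <- which(m & (!rbind(m[-1, ], FALSE) | !rbind(FALSE, m[-20, ]) |
                     !cbind(m[, -1], FALSE) | !cbind(FALSE, m[, -20])),
                arr.ind = TRUE)
  expect_setequal(paste(b[, "y"], b[, "x"]), paste(edge[, 1], edge[, 2]))
  ## single-pixel object
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  lb <- labelObjects(one, DetectorConfig(), 1)$boundaries[[1L]]
  expect_identical(nrow(lb), 1L)
})

test_that("mean single-cell area estimation is robust to noise and constant cases", {
  cfg <- DetectorConfig()
  expect_identical(estimateMeanSingleArea(rep(60, 10), cfg), 60)
  expect_identical(estimateMeanSingleArea(c(58, 60, 62, 5), cfg), 60)
  expect_error(estimateMeanSingleArea(numeric(0), cfg), "minObjectArea")
  expect_error(estimateMeanSingleArea(c(3, 8, 12), cfg), "minObjectArea")
  ## clusters present: estimate stays at the single-cell scale
  areas <- c(rep(60, 20), 125, 130, 190)
  expect_lt(abs(estimateMeanSingleArea(areas, cfg) - 60), 1)
})

test_that("classification applies the size rules and the half-up tie", {
  cfg <- DetectorConfig()   # minObjectArea 20, clusterFactor 1.5
  obj <- data.frame(objectId = 1:5, areaUm2 = c(10, 66, 120, 205, 150))
  cls <- classifyObjects(obj, meanSingleArea = 60, cfg)
  expect_identical(cls$label, c("noise", "single", "cluster", "cluster", "cluster"))
  expect_identical(cls$estimatedCells, c(0L, 1L, 2L, 3L, 3L))  # 150/60 = 2.5 -> 3
  expect_error(classifyObjects(obj, 0, cfg), "positive")

  ## monotone: estimated cells never decrease with area
  set.seed(3)
  a <- sort(runif(200, 0, 800))
  est <- classifyObjects(data.frame(objectId = seq_along(a), areaUm2 = a),
                         60, cfg)$estimatedCells
  expect_true(all(diff(est) >= 0))
})

test_that("a blank segment counts zero cells and a constant one errors under Otsu", {
  blank <- MosaicImage(matrix(20, 100, 100), 1)
  cfg <- DetectorConfig(thresholdMode = "manual", manualThreshold = 50,
                        smoothingRadius = 0)
  sc <- countSegment(blank, cfg)
  expect_identical(nTotalCells(sc), 0L)
  expect_error(countSegment(blank, DetectorConfig(smoothingRadius = 0)),
               "constant")
})

test_that("counting recovers planted clean scenes exactly", {
  ## 50 well-separated uniform cells
  sc50 <- generateSegment(cleanSpec(5, density = 50 / 0.1225))
  expect_identical(trueCount(sc50$truth), 50L)
  expect_identical(nTotalCells(countSegment(sc50$image, trace = FALSE)), 50L)

  ## 48 singles plus two touching pairs: cluster splitting adds 2 x 2
  spPair <- SyntheticSpec(density = 52 / 0.1225, cellRadiusCV = 0,
                          overlapPairFraction = 4 / 52, noiseSd = 2.8,
                          minSeparation = 14, seed = 9)
  scene <- generateSegment(spPair)
  expect_identical(trueCount(scene$truth), 52L)
  expect_identical(sum(!is.na(scene$truth@pairId)), 4L)
  cnt <- countSegment(scene$image, trace = FALSE)
  expect_identical(nTotalCells(cnt), 52L)
  expect_identical(cnt@nClusterObjects, 2L)

  ## exactness across seeds
  for (s in 11:15) {
    sc <- generateSegment(cleanSpec(s))
    expect_identical(nTotalCells(countSegment(sc$image, trace = FALSE)),
                     trueCount(sc$truth))
  }
})

test_that("counting is deterministic and invariant to right-angle rotation and mirroring", {
  scene <- generateSegment(cleanSpec(21, density = 900))
  img <- scene$image
  a <- countSegment(img, trace = FALSE)
  b <- countSegment(img, trace = FALSE)
  expect_identical(objectTable(a), objectTable(b))
  expect_identical(thresholdUsed(a), thresholdUsed(b))

  p <- pixels(img)
  rot90 <- MosaicImage(t(p)[, nrow(p):1], pixelSize(img))
  mirror <- MosaicImage(p[, ncol(p):1], pixelSize(img))
  expect_identical(nTotalCells(countSegment(rot90, trace = FALSE)),
                   nTotalCells(a))
  expect_identical(nTotalCells(countSegment(mirror, trace = FALSE)),
                   nTotalCells(a))
})

test_that("count conservation holds on every counted scene", {
  for (s in 1:3) {
    scene <- generateSegment(SyntheticSpec(density = 2500, seed = s))
    sc <- countSegment(scene$image, trace = FALSE)
    o <- objectTable(sc)
    expect_identical(nTotalCells(sc),
                     sum(o$label == "single") +
                       sum(o$estimatedCells[o$label == "cluster"]))
    expect_gte(nTotalCells(sc), sc@nSingles)
  }
})

test_that("pipeline counts equal the analytic archetype count", {
  widths <- c(rep(8L, 10), 12L, 16L, 10L, 13L, 8L, 20L, 4L)
  heights <- c(rep(8L, 10), 8L, 8L, 16L, 16L, 30L, 20L, 4L)
  sc <- archetypeScene(widths, heights)
  cfg <- archetypeConfig()
  cnt <- countSegment(sc$image, cfg, trace = FALSE)
  m <- estimateMeanSingleArea(sc$areas, cfg)
  expect_identical(m, 64)
  expect_identical(nTotalCells(cnt), as.integer(analyticCount(sc$areas, m, cfg)))
  ## spot check the composition: 11 singles (areas 64 and 96), clusters
  ## 128 -> 2, 160 -> 3 (tie up), 208 -> 3, 240 -> 4, 400 -> 6, noise 16 -> 0
  expect_identical(nTotalCells(cnt), 29L)
})

test_that("the overlay has annotation colors where objects are", {
  scene <- generateSegment(cleanSpec(31, density = 300))
  sc <- countSegment(scene$image)
  ov <- overlayImage(scene$image, sc)
  expect_identical(dim(ov), c(dim(scene$image), 3L))
  expect_true(any(ov[, , 1] == 1 & ov[, , 2] == 0))   # red marks present
})
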
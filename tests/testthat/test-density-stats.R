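# Densities, per-retina aggregation, and the study statistics.

test_that("density conversion is exact and scale-correct", {
  expect_identical(cellDensity(0, 350), 0)
  expect_equal(cellDensity(49, 350), 400)
  expect_equal(cellDensity(451, 350), 451 / 0.1225)   # 3681.6 cells/mm^2
  expect_error(cellDensity(10, 0), "sideUm")
  expect_error(cellDensity(-1, 350), ">= 0")
  ## halving the side quadruples the density
  expect_equal(cellDensity(80, 175), 4 * cellDensity(80, 350))
  ## linear in count
  expect_equal(cellDensity(2 * 37, 350), 2 * cellDensity(37, 350))
})

test_that("retina summaries average the 12 segments and their bands", {
  flat <- makeCountTable(rep(60L, 12))
  s <- summarizeRetina(flat, animalId = "m1")
  expect_equal(meanDensity(s), cellDensity(60, 350))
  expect_true(all(regionalMeans(s) == cellDensity(60, 350)))

  ## a planted central > middle > peripheral gradient
  grid <- expand.grid(quadrant = 1:4,
                      eccentricity = c("central", "middle", "peripheral"),
                      stringsAsFactors = FALSE)
  g <- data.frame(grid,
                  count = ifelse(grid$eccentricity == "central", 490L,
                                 ifelse(grid$eccentricity == "middle",
                                        368L, 245L)))
  s2 <- summarizeRetina(g)
  expect_equal(unname(regionalMeans(s2)["central"]), cellDensity(490, 350))
  expect_equal(meanDensity(s2), mean(cellDensity(c(490, 368, 245), 350)))
  ## permutation invariance
  s3 <- summarizeRetina(g[sample(12), ])
  expect_equal(meanDensity(s3), meanDensity(s2))

  expect_error(summarizeRetina(g[-1, ]), "12")
  dup <- g; dup$quadrant[1] <- 2L
  expect_error(summarizeRetina(dup), "exactly once")
})

test_that("two-group comparison matches the reference t test to 6+ digits", {
  a <- c(3560, 3712, 3833, 3595, 3644, 3701, 3580, 3690)
  b <- c(2120, 2445, 2210, 2350, 2295, 2180, 2460, 2240, 2322, 2150, 2401)
  res <- compareTwoGroups(a, b, labels = c("CFA", "EAE"))
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$pValue, ref$p.value, tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$means, c(mean(a), mean(b)))
  expect_equal(res$sems, c(sd(a) / sqrt(8), sd(b) / sqrt(11)))

  w <- compareTwoGroups(a, b, varEqual = FALSE)
  refw <- t.test(a, b)
  expect_equal(w$pValue, refw$p.value, tolerance = 1e-10)

  ## symmetric up to sign
  swapped <- compareTwoGroups(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$pValue, res$pValue)

  ## identical groups: statistic 0, p 1 (documented convention)
  same <- compareTwoGroups(c(5, 5, 5), c(5, 5, 5))
  expect_identical(same$statistic, 0)
  expect_identical(same$pValue, 1)

  ## a clear shift is significant
  sh <- compareTwoGroups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sh$pValue, 0.01)

  expect_error(compareTwoGroups(c(1), c(1, 2)), "at least 2")
})

test_that("multi-group comparison reproduces ANOVA and Tukey HSD", {
  g <- list(naive = c(3700, 3650, 3805, 3590, 3744),
            CFA = c(3683, 3760, 3601, 3555, 3810),
            EAE = c(2272, 2410, 2150, 2333, 2190))
  res <- compareMultiGroups(g)
  y <- unlist(g); f <- factor(rep(names(g), each = 5), levels = names(g))
  fit <- aov(y ~ f)
  s <- summary(fit)[[1]]
  expect_equal(res$statistic, s[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$pValue, s[["Pr(>F)"]][1], tolerance = 1e-10)
  tk <- TukeyHSD(fit)$f
  expect_equal(res$tukey$pAdj, unname(tk[, "p adj"]), tolerance = 1e-10)
  expect_equal(res$tukey$diff, unname(tk[, "diff"]), tolerance = 1e-10)

  ## only contrasts against the shifted group are significant
  sig <- res$tukey$pAdj < 0.05
  names(sig) <- res$tukey$pair
  expect_false(sig[["CFA-naive"]])
  expect_true(sig[["EAE-naive"]])
  expect_true(sig[["EAE-CFA"]])

  ## three identical groups: F = 0, all Tukey p = 1
  same <- compareMultiGroups(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                  c = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)
  expect_true(all(same$tukey$pAdj == 1))

  expect_error(compareMultiGroups(list(a = 1:3, b = 1:3)), "compareTwoGroups")
})

test_that("Spearman correlation matches cor.test in both p-value regimes", {
  ## exact branch (n <= 9, no ties)
  x <- c(3.2, 1.1, 4.8, 2.7, 5.9, 0.4, 3.9)
  y <- c(2.5, 3.8, 1.9, 2.9, 0.7, 4.4, 1.2)
  res <- spearmanCorrelation(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$pValue, ref$p.value, tolerance = 1e-10)

  ## asymptotic branch (n >= 10)
  set.seed(8)
  x2 <- rnorm(14); y2 <- 0.6 * x2 + rnorm(14, 0, 0.8)
  res2 <- spearmanCorrelation(x2, y2)
  ref2 <- cor.test(x2, y2, method = "spearman", exact = FALSE)
  expect_equal(res2$rho, unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(res2$pValue, ref2$p.value, tolerance = 1e-10)

  ## strictly monotone: rho is exactly -1
  mono <- spearmanCorrelation(c(0, 1, 2, 3), c(40, 30, 20, 10))
  expect_equal(mono$rho, -1)

  ## aligned ties still give -1 (average ranks)
  tie <- spearmanCorrelation(c(4, 4, 2, 1), c(0, 0, 2, 3))
  expect_equal(tie$rho, -1)

  ## invariance under strictly monotone transforms
  res3 <- spearmanCorrelation(exp(x), y^3)
  expect_equal(res3$rho, res$rho)
  expect_equal(res3$pValue, res$pValue)

  expect_error(spearmanCorrelation(c(1, 1, 1, 1), c(1, 2, 3, 4)),
               "degenerate")
  expect_error(spearmanCorrelation(c(1, 2), c(3, 4)), "at least 3")
})

test_that("density-score correlation matches animals by id", {
  rec <- data.frame(animal_id = c("a", "b", "c", "d"),
                    group = "EAE", peak_behavior_score = c(0, 1, 2, 3),
                    sex = NA_character_, stringsAsFactors = FALSE)
  dens <- data.frame(animal_id = c("d", "c", "b", "a"),
                     mean_density = c(1000, 2000, 3000, 4000))
  res <- correlateWithScore(dens, rec)
  expect_equal(res$rho, -1)
  expect_identical(res$nPairs, 4L)

  bad <- dens; bad$animal_id[1] <- "zz"
  expect_error(correlateWithScore(bad, rec), "matched")
})

test_that("auto-vs-manual agreement reports bias and paired significance", {
  manual <- makeCountTable(c(52L, 49L, 50L, 48L, 45L, 44L, 46L, 43L,
                             38L, 40L, 39L, 41L))
  same <- agreementAutoManual(manual, manual)
  expect_identical(same$meanBias, 0)
  expect_identical(same$pairedPValue, 1)
  expect_true(all(same$differences$diff == 0))

  shifted <- manual
  shifted$count <- shifted$count + 5L
  shifted$density <- cellDensity(shifted$count, 350)
  res <- agreementAutoManual(shifted, manual)
  expect_identical(res$meanBias, 5)
  expect_true(all(res$differences$diff == 5L))
  expect_identical(res$byRegion$meanDiff, rep(5, 3))

  other <- manual
  other$animal_id <- "m2"
  expect_error(agreementAutoManual(other, manual), "identical")
})
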
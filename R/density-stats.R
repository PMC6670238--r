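#' @include AllClasses.R
NULL

#' Convert a segment count to a density
#'
#' @param count non-negative cell count.
#' @param sideUm segment edge length in micrometres.
#' @return density in cells/mm^2: \code{count / (sideUm/1000)^2}.
#' @examples
#' cellDensity(49, 350)   # 400
#' cellDensity(451, 350)  # 3681.6
#' @export
cellDensity <- function(count, sideUm = 350) {
  if (any(!is.finite(sideUm)) || any(sideUm <= 0))
    stop("sideUm must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / (sideUm / 1000)^2
}

#' Summarize the twelve segments of one retina
#'
#' The per-retina RGC density is the arithmetic mean of the twelve segment
#' densities; regional means average the four quadrants of each eccentricity
#' band. Exactly one count per (quadrant, eccentricity) is required.
#'
#' @param counts data frame with columns \code{quadrant},
#'   \code{eccentricity} and \code{count} (a count table works as is).
#' @param sideUm segment edge length used for the densities.
#' @param animalId,eye identifiers carried into the summary.
#' @return a \linkS4class{RetinaSummary}.
#' @export
summarizeRetina <- function(counts, sideUm = 350, animalId = "", eye = "left") {
  if (!is.data.frame(counts) ||
      !all(c("quadrant", "eccentricity", "count") %in% names(counts)))
    stop("counts must have quadrant, eccentricity and count columns")
  if (nrow(counts) != 12L)
    stop("a retina summary needs exactly 12 labeled segment counts, got ",
         nrow(counts))
  key <- paste(counts$quadrant, counts$eccentricity)
  want <- as.vector(outer(1:4, .eccLevels, paste))
  if (!setequal(key, want) || anyDuplicated(key))
    stop("counts must cover each (quadrant, eccentricity) exactly once")
  d <- data.frame(quadrant = counts$quadrant,
                  eccentricity = counts$eccentricity,
                  count = counts$count,
                  density = cellDensity(counts$count, sideUm),
                  stringsAsFactors = FALSE)
  rm2 <- vapply(.eccLevels,
                function(e) mean(d$density[d$eccentricity == e]), numeric(1L))
  new("RetinaSummary", densities = d, meanDensity = mean(d$density),
      regionalMeans = rm2, animalId = as.character(animalId),
      eye = as.character(eye), sideUm = as.numeric(sideUm))
}

## mean +/- SEM of a numeric vector
.sem <- function(x) sd(x) / sqrt(length(x))

#' Compare two groups of densities
#'
#' Unpaired two-tailed t test (equal variances by default, matching the
#' classical Student test; Welch via \code{varEqual = FALSE}), reporting
#' group means with SEMs. Two groups with zero variance and equal means
#' yield p = 1 by convention; zero variance with different means yields
#' p = 0.
#'
#' @param a,b numeric vectors of per-animal densities, each of length >= 2.
#' @param labels group names for the report.
#' @param varEqual pool the variances (classical t test) or not (Welch).
#' @return list with \code{groupLabels}, \code{means}, \code{sems},
#'   \code{n}, \code{statistic}, \code{df}, \code{pValue}, \code{method}.
#' @export
compareTwoGroups <- function(a, b, labels = c("A", "B"), varEqual = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  base <- list(groupLabels = labels, means = c(mean(a), mean(b)),
               sems = c(.sem(a), .sem(b)), n = c(length(a), length(b)),
               method = if (varEqual) "Two-tailed unpaired Student t test"
                        else "Two-tailed Welch t test")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(c(base, list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                        df = length(a) + length(b) - 2L,
                        pValue = if (eq) 1 else 0)))
  }
  tt <- t.test(a, b, var.equal = varEqual)
  c(base, list(statistic = unname(tt$statistic), df = unname(tt$parameter),
               pValue = tt$p.value))
}

#' Compare three or more groups of densities
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' for all pairwise contrasts.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @return list with \code{groupLabels}, \code{means}, \code{sems},
#'   \code{n}, \code{statistic} (the F value), \code{df} (numerator,
#'   denominator), \code{pValue}, and \code{tukey}, a data frame of pairwise
#'   differences with adjusted p values.
#' @export
compareMultiGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need at least 3 groups; use compareTwoGroups() for two")
  if (is.null(names(groups))) names(groups) <- LETTERS[seq_along(groups)]
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1L))),
              levels = names(groups))
  fit <- aov(y ~ g)
  s <- summary(fit)[[1L]]
  Fv <- s[["F value"]][1L]
  p <- s[["Pr(>F)"]][1L]
  if (!is.finite(Fv)) {    # all observations identical
    Fv <- 0; p <- 1
  }
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      pAdj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (!all(is.finite(tukey$pAdj))) tukey$pAdj[!is.finite(tukey$pAdj)] <- 1
  list(groupLabels = names(groups),
       means = vapply(groups, mean, numeric(1L)),
       sems = vapply(groups, .sem, numeric(1L)),
       n = vapply(groups, length, integer(1L)),
       statistic = Fv, df = c(s[["Df"]][1L], s[["Df"]][2L]), pValue = p,
       tukey = tukey, method = "One-way ANOVA with Tukey HSD")
}

## all permutations of 1..n as an (n!) x n matrix
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .permMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, p + (p >= i))))
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling. The two-sided p value
#' uses exact permutation enumeration for n <= 9 (small animal cohorts; the
#' enumeration handles ties, which the classical exact tables do not) and
#' the t-distribution approximation for larger n.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with \code{rho}, \code{pValue}, \code{nPairs},
#'   \code{method}.
#' @export
spearmanCorrelation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("degenerate ranks: one variable is constant, rho is undefined")
  rho <- cor(rx, ry)
  if (n <= 9L) {
    P <- .permMatrix(n)
    M <- matrix(rx[P], nrow(P), n)
    s <- as.vector(M %*% ry)
    mu <- n * mean(rx) * mean(ry)
    denom <- (n - 1L) * sd(rx) * sd(ry)
    rhos <- (s - mu) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation, exact permutation p"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (is.finite(tstat)) 2 * pt(-abs(tstat), n - 2) else 0
    method <- "Spearman rank correlation, t approximation"
  }
  list(rho = rho, pValue = min(1, p), nPairs = n, method = method)
}

#' Correlate per-animal densities with peak behavior scores
#'
#' Animals are matched by id between the density summaries and the clinical
#' records; the Spearman rank correlation of mean RGC density against peak
#' behavior score is returned (disease severity is expected to correlate
#' negatively with surviving RGC density).
#'
#' @param summaries data frame with \code{animal_id} and
#'   \code{mean_density}, or a named numeric vector of densities.
#' @param records animal records (see \code{\link{validateAnimalRecords}}).
#' @return as \code{\link{spearmanCorrelation}}.
#' @export
correlateWithScore <- function(summaries, records) {
  if (!is.data.frame(summaries)) {
    summaries <- data.frame(animal_id = names(summaries),
                            mean_density = as.numeric(summaries),
                            stringsAsFactors = FALSE)
  }
  validateAnimalRecords(records)
  m <- merge(summaries, records, by = "animal_id")
  if (nrow(m) < nrow(summaries) || nrow(m) < 3L)
    stop("need at least 3 animals matched by id between summaries and records")
  spearmanCorrelation(m$mean_density, m$peak_behavior_score)
}

#' Agreement between automated and manual counts
#'
#' Paired comparison of two count tables over identical segment keys
#' (animal, eye, quadrant, eccentricity, and timepoint when present):
#' per-segment differences (auto - manual), mean bias, a paired two-tailed
#' t test, and a per-eccentricity breakdown.
#'
#' @param auto,manual count tables sharing identical keys.
#' @return list with \code{differences} (data frame), \code{meanBias},
#'   \code{pairedPValue}, \code{n} and \code{byRegion}.
#' @export
agreementAutoManual <- function(auto, manual) {
  keys <- c("animal_id", "eye", "quadrant", "eccentricity")
  if ("timepoint" %in% names(auto) && "timepoint" %in% names(manual))
    keys <- c(keys, "timepoint")
  ka <- do.call(paste, auto[keys])
  km <- do.call(paste, manual[keys])
  if (!setequal(ka, km) || anyDuplicated(ka) || anyDuplicated(km))
    stop("the two tables must cover identical segment keys exactly once")
  m <- merge(auto[, c(keys, "count")], manual[, c(keys, "count")],
             by = keys, suffixes = c("_auto", "_manual"))
  d <- m$count_auto - m$count_manual
  pairedP <- function(di) {
    if (length(di) < 2L) return(NA_real_)
    if (sd(di) == 0) return(if (mean(di) == 0) 1 else 0)
    t.test(di)$p.value
  }
  byRegion <- do.call(rbind, lapply(.eccLevels, function(e) {
    de <- d[m$eccentricity == e]
    data.frame(eccentricity = e, n = length(de), meanDiff = mean(de),
               pValue = pairedP(de), stringsAsFactors = FALSE)
  }))
  list(differences = cbind(m[keys], diff = d), meanBias = mean(d),
       pairedPValue = pairedP(d), n = length(d), byRegion = byRegion,
       method = "Paired two-tailed t test on per-segment counts")
}
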
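# Internal helpers shared across modules.

## round-half-up: the tie rule used when splitting clusters (2.5 -> 3).
roundHalfUp <- function(x) floor(x + 0.5)

## Evaluate expr under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Otsu threshold on a 256-bin histogram over the observed intensity range.
## The returned value t is meant for strict binarization (intensity > t): it
## is placed midway between the largest background and smallest foreground
## intensity so the split is exactly the between-class-variance optimum.
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("automatic thresholding needs a non-constant image")
  edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  h <- tabulate(bin, nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  W <- cumsum(as.numeric(h))
  M <- cumsum(h * mids)
  total <- W[nbins]
  w0 <- W[-nbins]
  w1 <- total - w0
  mu0 <- M[-nbins] / w0
  mu1 <- (M[nbins] - M[-nbins]) / w1
  bc <- w0 * w1 * (mu0 - mu1)^2
  bc[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bc)            # background = bins 1..k
  bg <- v[bin <= k]
  fg <- v[bin > k]
  (max(bg) + min(fg)) / 2
}

## Connected-component labeling of a logical mask under 4- or 8-connectivity.
## Two-pass run-length scheme: runs of foreground pixels are found per
## column, runs in adjacent columns are merged with union-find when their row
## ranges touch (dilated by one row for 8-connectivity), and final labels are
## numbered in first-appearance (column-major) order. Returns an integer
## matrix, 0 = background.
labelMask <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask > 0
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  starts <- vector("list", nc)
  ends <- vector("list", nc)
  nrun <- integer(nc)
  for (j in seq_len(nc)) {
    r <- rle(mask[, j])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values
    starts[[j]] <- s[keep]
    ends[[j]] <- e[keep]
    nrun[j] <- sum(keep)
  }
  total <- sum(nrun)
  if (total == 0L) return(matrix(0L, nr, nc))
  parent <- seq_len(total)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- cumsum(c(0L, nrun))
  d <- if (connectivity == 8L) 1L else 0L
  for (j in seq_len(nc)[-1L]) {
    na <- nrun[j - 1L]; nb <- nrun[j]
    if (na == 0L || nb == 0L) next
    sa <- starts[[j - 1L]]; ea <- ends[[j - 1L]]
    sb <- starts[[j]]; eb <- ends[[j]]
    a <- 1L; b <- 1L
    while (a <= na && b <= nb) {
      if (sa[a] <= eb[b] + d && sb[b] <= ea[a] + d) {
        ra <- findRoot(off[j] - nrun[j - 1L] + a)
        rb <- findRoot(off[j] + b)
        if (ra != rb) parent[rb] <- ra
      }
      if (ea[a] < eb[b]) a <- a + 1L else b <- b + 1L
    }
  }
  roots <- vapply(seq_len(total), findRoot, integer(1L))
  newId <- match(roots, unique(roots))
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) {
    if (nrun[j] == 0L) next
    s <- starts[[j]]; e <- ends[[j]]
    for (i in seq_along(s)) {
      k <- k + 1L
      lab[s[i]:e[i], j] <- newId[k]
    }
  }
  lab
}

## Moore-neighbor contour tracing of a single object inside a labeled matrix.
## Returns an ordered two-column (x = col, y = row) matrix of the outer
## boundary pixels, clockwise in image coordinates.
traceBoundary <- function(lab, id) {
  hit <- which(lab == id)
  if (!length(hit)) stop("no such object id")
  nr <- nrow(lab)
  ## first pixel in column-major order; its predecessor in the scan is
  ## background, giving the initial backtrack direction
  p0 <- hit[1L]
  r0 <- (p0 - 1L) %% nr + 1L
  c0 <- (p0 - 1L) %/% nr + 1L
  ## clockwise 8-neighborhood starting west (dr, dc)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= ncol(lab) &&
    lab[r, c] == id
  if (!any(vapply(1:8, function(k) inside(r0 + dr[k], c0 + dc[k]), logical(1L))))
    return(cbind(x = c0, y = r0))           # isolated single pixel
  out <- matrix(0L, 64L, 2L)
  nout <- 0L
  push <- function(r, c) {
    nout <<- nout + 1L
    if (nout > nrow(out)) out <<- rbind(out, matrix(0L, nrow(out), 2L))
    out[nout, ] <<- c(c, r)
  }
  push(r0, c0)
  cr <- r0; cc <- c0
  ## `back` is the clockwise index of the background pixel we arrived from;
  ## the scan resumes there and proceeds clockwise. The scan predecessor of
  ## the start pixel is its northern neighbor (index 3), which is background.
  back <- 3L
  limit <- 4L * length(hit) + 8L
  for (step in seq_len(limit)) {
    found <- FALSE
    for (k in 0:7) {
      dir <- (back + k - 1L) %% 8L + 1L
      nr2 <- cr + dr[dir]; nc2 <- cc + dc[dir]
      if (inside(nr2, nc2)) {
        prevDir <- (back + k - 2L) %% 8L + 1L   # last background examined
        pr <- cr + dr[prevDir]; pc <- cc + dc[prevDir]
        cr <- nr2; cc <- nc2
        back <- .dirIndex(pr - cr, pc - cc)
        found <- TRUE
        break
      }
    }
    if (!found || (cr == r0 && cc == c0)) break
    push(cr, cc)
  }
  m <- out[seq_len(nout), , drop = FALSE]
  colnames(m) <- c("x", "y")
  unique(m)
}

## clockwise index of the neighbor at offset (dr, dc) from the current pixel
.dirIndex <- function(dr, dc) {
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  which(drs == dr & dcs == dc)[1L]
}

## Per-object areas and centroids from a label matrix.
componentStats <- function(lab, pixelSize) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(objectId = integer(0), areaPx = integer(0),
                      areaUm2 = numeric(0), centroidX = numeric(0),
                      centroidY = numeric(0)))
  l <- lab[idx]
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  n <- max(l)
  areaPx <- tabulate(l, n)
  cx <- rowsum(as.numeric(cols), l)[, 1L] / areaPx
  cy <- rowsum(as.numeric(rows), l)[, 1L] / areaPx
  data.frame(objectId = seq_len(n), areaPx = areaPx,
             areaUm2 = areaPx * pixelSize^2, centroidX = as.numeric(cx),
             centroidY = as.numeric(cy))
}
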
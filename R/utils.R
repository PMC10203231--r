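## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards so generators are pure functions of their
## arguments.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Separable Gaussian smoothing of a 3D array; fwhm and voxelSize in mm.
## Used for the optional pre-GLM spatial filter (gas-challenge conventions).
gaussianSmooth3d <- function(x, fwhm, voxelSize) {
  stopifnot(length(dim(x)) == 3L)
  if (fwhm <= 0) return(x)
  voxelSize <- rep_len(voxelSize, 3L)
  for (ax in 1:3) {
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize[ax]
    if (sigma < 1e-6) next
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-half:half) / sigma)^2)
    k <- k / sum(k)
    x <- convolveAlong(x, k, ax)
  }
  x
}

convolveAlong <- function(x, k, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  half <- (length(k) - 1L) / 2L
  n <- dp[1]
  ## replicate-pad edges so constant inputs are preserved
  idx <- c(rep(1L, half), seq_len(n), rep(n, half))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  res <- array(out, dp)
  aperm(res, order(perm))
}

## Label connected components (6-connectivity) of a 3D logical array.
## Returns an integer array; 0 = background. Grids here are small, so a
## plain BFS over the suprathreshold voxels is adequate.
connectedComponents <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coord <- arrayInd(idx, d)
  lookup <- array(0L, d)
  lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  current <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(idx)) {
    if (visited[s]) next
    current <- current + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      lab[idx[v]] <- current
      for (o in 1:6) {
        nb <- coord[v, ] + offs[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        j <- lookup[nb[1], nb[2], nb[3]]
        if (j > 0L && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

## Local-maximum detection with minimum separation and prominence rules.
## Prominence of a candidate peak = height minus the higher of the two
## valley floors separating it from the nearest taller samples.
findProminentPeaks <- function(x, minSeparation, minProminence, dt) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > min(x)]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (any(x[seq_len(i - 1)] > h)) {
      j <- max(which(x[seq_len(i - 1)] > h))
      min(x[j:i])
    } else min(x[1:i])
    right <- if (any(x[(i + 1):n] > h)) {
      j <- i + min(which(x[(i + 1):n] > h))
      min(x[i:j])
    } else min(x[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= minProminence]
  if (!length(keep)) return(integer(0))
  ## enforce minimum separation, keeping taller peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  minGap <- minSeparation / dt
  for (i in ord)
    if (!length(sel) || all(abs(sel - i) >= minGap)) sel <- c(sel, i)
  sort(sel)
}

fmtPct <- function(k, n, digits = 1) round(100 * k / n, digits)
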
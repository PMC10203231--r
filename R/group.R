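#' @include AllClasses.R utils.R
NULL

stackImages <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  stopifnot(is.list(images), length(images) >= 1L)
  d <- dim(images[[1]])
  arr <- array(NA_real_, c(d, length(images)))
  for (i in seq_along(images)) {
    stopifnot(identical(dim(images[[i]]), d))
    arr[, , , i] <- images[[i]]
  }
  arr
}

#' Group-level one-sample t map
#'
#' Per-voxel one-sample t-test on the subject contrast values (dof n - 1).
#' Voxels with zero between-subject variance, or any missing subject
#' value, are masked with a logged count.
#'
#' @param contrastImages list of 3D subject contrast arrays (or a 4D array
#'   with subjects last). NA voxels propagate to the mask.
#' @param mask optional logical 3D array restricting the analysis.
#' @return A \linkS4class{StatMap} with one-sided upper-tail p-values.
#' @export
groupTTest <- function(contrastImages, mask = NULL) {
  arr <- stackImages(contrastImages)
  n <- dim(arr)[4]
  if (n < 3) stop("group t-test needs >= 3 subjects")
  d <- dim(arr)[1:3]
  Y <- matrix(arr, nrow = prod(d))
  ok <- rowSums(is.na(Y)) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  mu <- rowMeans(Y)
  s2 <- rowSums((Y - mu)^2) / (n - 1)
  degen <- ok & s2 <= 0
  if (any(degen))
    message(sprintf("groupTTest: masking %d zero-variance voxel(s)",
                    sum(degen)))
  ok <- ok & s2 > 0
  tv <- rep(NA_real_, length(mu))
  tv[ok] <- mu[ok] / sqrt(s2[ok] / n)
  p <- stats::pt(tv, df = n - 1, lower.tail = FALSE)
  new("StatMap", t = array(tv, d), p = array(p, d),
      contrast = 1, dof = n - 1, mask = array(ok, d))
}

#' Voxel-wise image-covariate corrected group map
#'
#' At every voxel, models the subject contrast values on an intercept and
#' the mean-centred covariate values at that voxel (a separate GLM per
#' voxel), reporting the intercept t — the group mean effect adjusted for
#' the vascular covariate — with dof n - 2. Voxels where the covariate has
#' zero variance fall back to the uncorrected one-sample model and are
#' flagged.
#'
#' @param contrastImages,covariateImages lists of aligned 3D subject
#'   arrays (or 4D arrays, subjects last).
#' @param mask optional logical 3D restriction.
#' @return A \linkS4class{StatMap}; \code{attr(, "fallbackVoxels")} counts
#'   zero-variance-covariate voxels.
#' @export
voxelwiseCovariateCorrection <- function(contrastImages, covariateImages,
                                         mask = NULL) {
  Yarr <- stackImages(contrastImages)
  Carr <- stackImages(covariateImages)
  stopifnot(identical(dim(Yarr), dim(Carr)))
  n <- dim(Yarr)[4]
  if (n < 4) stop("covariate correction needs >= 4 subjects")
  d <- dim(Yarr)[1:3]
  Y <- matrix(Yarr, nrow = prod(d))
  C <- matrix(Carr, nrow = prod(d))
  ok <- rowSums(is.na(Y)) == 0 & rowSums(is.na(C)) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  Cc <- C - rowMeans(C)
  Sxx <- rowSums(Cc^2)
  varY <- rowSums((Y - rowMeans(Y))^2)
  zeroCov <- ok & Sxx <= 0
  mu <- rowMeans(Y)
  slope <- ifelse(Sxx > 0, rowSums(Cc * Y) / Sxx, 0)
  res <- Y - mu - Cc * slope
  rss <- rowSums(res^2)
  tv <- rep(NA_real_, length(mu))
  ## corrected model: intercept se = sqrt(sigma2 / n) (centred covariate)
  use <- ok & Sxx > 0
  sigma2 <- rss / (n - 2)
  good <- use & sigma2 > 0
  tv[good] <- mu[good] / sqrt(sigma2[good] / n)
  ## fallback: plain one-sample where the covariate is degenerate
  s2 <- varY / (n - 1)
  fb <- zeroCov & s2 > 0
  tv[fb] <- mu[fb] / sqrt(s2[fb] / n)
  dof <- n - 2
  p <- stats::pt(tv, df = dof, lower.tail = FALSE)
  p[fb] <- stats::pt(tv[fb], df = n - 1, lower.tail = FALSE)
  okAll <- (good | fb)
  tvArr <- array(tv, d); tvArr[!okAll] <- NA_real_
  pArr <- array(p, d); pArr[!okAll] <- NA_real_
  out <- new("StatMap", t = tvArr, p = pArr, contrast = 1, dof = dof,
             mask = array(okAll, d))
  attr(out, "fallbackVoxels") <- sum(fb)
  out
}

#' ROI-covariate corrected group map
#'
#' Within each region's binary mask, fits the one-sample model with one
#' mean-centred scalar covariate per subject (the subject's averaged
#' vascular value for that region) and reports the intercept t with
#' dof n - 2. Regions absent from \code{roiValues} are absent from the
#' output.
#'
#' @param contrastImages list/4D array of subject contrast maps.
#' @param roiValues matrix subjects x regions (column names = region
#'   labels) of scalar covariates.
#' @param atlas an \linkS4class{AtlasPhantom} supplying the region masks.
#' @param labels regions to analyze; default the columns of
#'   \code{roiValues}.
#' @return A \linkS4class{StatMap} defined inside the union of the region
#'   masks.
#' @export
roiCovariateCorrection <- function(contrastImages, roiValues, atlas,
                                   labels = NULL) {
  arr <- stackImages(contrastImages)
  n <- dim(arr)[4]
  if (n < 4) stop("covariate correction needs >= 4 subjects")
  stopifnot(is(atlas, "AtlasPhantom"))
  labs <- labels %||% as.integer(colnames(roiValues))
  if (!length(labs)) stop("no region labels supplied")
  d <- dim(arr)[1:3]
  tv <- array(NA_real_, d); pv <- array(NA_real_, d)
  mk <- array(FALSE, d)
  Y <- matrix(arr, nrow = prod(d))
  for (lb in labs) {
    sel <- which(as.vector(atlas@labels == lb))
    if (!length(sel)) stop(sprintf("region %d has an empty mask", lb))
    cvec <- roiValues[, as.character(lb)]
    cc <- cvec - mean(cvec)
    Sxx <- sum(cc^2)
    Ys <- Y[sel, , drop = FALSE]
    mu <- rowMeans(Ys)
    if (Sxx > 0) {
      slope <- drop(Ys %*% cc) / Sxx
      rss <- rowSums((Ys - mu - outer(slope, cc))^2)
      sigma2 <- rss / (n - 2)
      okv <- sigma2 > 0
      tloc <- rep(NA_real_, length(mu))
      tloc[okv] <- mu[okv] / sqrt(sigma2[okv] / n)
      ploc <- stats::pt(tloc, df = n - 2, lower.tail = FALSE)
    } else {
      s2 <- rowSums((Ys - mu)^2) / (n - 1)
      okv <- s2 > 0
      tloc <- rep(NA_real_, length(mu))
      tloc[okv] <- mu[okv] / sqrt(s2[okv] / n)
      ploc <- stats::pt(tloc, df = n - 1, lower.tail = FALSE)
    }
    tv[sel] <- tloc; pv[sel] <- ploc
    mk[sel[okv]] <- TRUE
  }
  new("StatMap", t = tv, p = pv, contrast = 1, dof = n - 2, mask = mk)
}

#' Permutation cluster-extent null
#'
#' Sign-flip permutation null for cluster-extent correction: at each
#' permutation the subject images are randomly sign-flipped, the
#' one-sample t map recomputed, thresholded at the cluster-forming p, and
#' the maximum 6-connected cluster extent recorded. The familywise
#' critical extent is the (1 - fwe) quantile of that null.
#'
#' @param contrastImages list/4D array of subject contrast maps.
#' @param clusterP cluster-forming voxel p (one-sided; default 0.005).
#' @param nPerm number of permutations (default 1000).
#' @param fwe familywise error level (default 0.05).
#' @param seed integer seed for the sign flips.
#' @return list with \code{critical_extent}, \code{null_max_extents},
#'   \code{clusterP}, \code{nPerm}.
#' @export
permutationClusterNull <- function(contrastImages, clusterP = 0.005,
                                   nPerm = 1000, fwe = 0.05, seed = 1) {
  arr <- stackImages(contrastImages)
  n <- dim(arr)[4]
  d <- dim(arr)[1:3]
  Y <- matrix(arr, nrow = prod(d))
  ok <- rowSums(is.na(Y)) == 0
  tcrit <- stats::qt(clusterP, df = n - 1, lower.tail = FALSE)
  withSeed(seed, {
    maxExt <- integer(nPerm)
    for (b in seq_len(nPerm)) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      Yb <- sweep(Y, 2, flips, `*`)
      mu <- rowMeans(Yb)
      s2 <- rowSums((Yb - mu)^2) / (n - 1)
      tv <- ifelse(ok & s2 > 0, mu / sqrt(s2 / n), NA_real_)
      supra <- array(!is.na(tv) & tv > tcrit, d)
      if (!any(supra)) { maxExt[b] <- 0L; next }
      lab <- connectedComponents(supra)
      maxExt[b] <- max(tabulate(lab[lab > 0]))
    }
    list(critical_extent = as.integer(
           stats::quantile(maxExt, 1 - fwe, type = 1)),
         null_max_extents = maxExt, clusterP = clusterP, nPerm = nPerm)
  })
}

#' Compare sensitivity across group-analysis modes
#'
#' Counts suprathreshold voxels (optionally after a cluster-extent rule)
#' and the peak t per mode on identical masks and thresholds, and reports
#' corrected-minus-uncorrected deltas against the mode named
#' \code{"uncorrected"}.
#'
#' @param maps named list of \linkS4class{StatMap}s, one per mode; must
#'   include \code{"uncorrected"}.
#' @param voxelP voxel threshold in (0, 1).
#' @param clusterExtent minimum cluster size in voxels (0 = plain voxel
#'   thresholding).
#' @return list with per-mode \code{n_suprathreshold} and \code{peak_t},
#'   plus \code{delta_voxels} and \code{delta_peak_t}.
#' @export
compareSensitivity <- function(maps, voxelP = 0.001, clusterExtent = 0) {
  if (voxelP <= 0 || voxelP >= 1) stop("'voxelP' must be in (0, 1)")
  stopifnot("uncorrected" %in% names(maps))
  shared <- Reduce(`&`, lapply(maps, function(m) m@mask))
  counts <- integer(0); peaks <- numeric(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    supra <- !is.na(m@p) & m@p < voxelP & shared
    if (clusterExtent > 0 && any(supra)) {
      lab <- connectedComponents(supra)
      sizes <- tabulate(lab[lab > 0])
      keepLab <- which(sizes >= clusterExtent)
      supra <- array(lab %in% keepLab & lab > 0, dim(supra))
    }
    counts[nm] <- sum(supra)
    peaks[nm] <- if (any(shared)) max(m@t[shared], na.rm = TRUE) else NA_real_
  }
  list(n_suprathreshold = as.list(counts), peak_t = as.list(peaks),
       delta_voxels = as.list(counts - counts[["uncorrected"]]),
       delta_peak_t = as.list(peaks - peaks[["uncorrected"]]))
}
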
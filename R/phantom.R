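#' @include AllClasses.R utils.R
NULL

#' Generate an atlas-labelled block phantom
#'
#' Carves a rectangular grid into connected rectangular-block parcels with
#' contiguous integer labels, emulating a cortical parcellation (default 68
#' regions). Blocks are formed by splitting each axis into near-equal
#' segments; when the axis split yields more blocks than parcels, the
#' parcel blocks are chosen (and labels ordered) by a seeded shuffle and
#' the remainder becomes background. Hemisphere assignment follows the
#' block's position along x.
#'
#' @param nParcels number of parcels (>= 2; default 68).
#' @param gridShape integer(3) voxel counts per axis.
#' @param seed integer seed.
#' @param voxelSize voxel edge length(s) in mm (default 3 mm isotropic).
#' @return An \linkS4class{AtlasPhantom}; every parcel has >= 20 voxels.
#' @examples
#' ph <- generatePhantom(8, c(12, 12, 8), seed = 1)
#' nParcels(ph)
#' @export
generatePhantom <- function(nParcels = 68, gridShape = c(24, 24, 18),
                            seed = 1, voxelSize = 3) {
  if (nParcels < 2) stop("'nParcels' must be >= 2")
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))
  minVox <- 20L
  if (prod(gridShape) < nParcels * minVox)
    stop(sprintf("grid too small: %d parcels need at least %d voxels (>= %d per parcel), grid has %d",
                 nParcels, nParcels * minVox, minVox, prod(gridShape)))
  split <- chooseAxisSplit(gridShape, nParcels, minVox)
  if (is.null(split))
    stop(sprintf("grid too small: no axis split gives %d blocks of >= %d voxels each on a %s grid",
                 nParcels, minVox, paste(gridShape, collapse = "x")))
  segs <- lapply(1:3, function(ax) axisSegments(gridShape[ax], split[ax]))
  blocks <- expand.grid(ix = seq_len(split[1]), iy = seq_len(split[2]),
                        iz = seq_len(split[3]))
  lab <- array(0L, gridShape)
  withSeed(seed, {
    chosen <- sample.int(nrow(blocks), nParcels)
    regionName <- character(nParcels)
    hemi <- character(nParcels)
    nvox <- integer(nParcels)
    for (k in seq_len(nParcels)) {
      b <- blocks[chosen[k], ]
      xs <- segs[[1]][[b$ix]]; ys <- segs[[2]][[b$iy]]; zs <- segs[[3]][[b$iz]]
      lab[xs, ys, zs] <- k
      nvox[k] <- length(xs) * length(ys) * length(zs)
      hemi[k] <- if (mean(xs) <= gridShape[1] / 2) "L" else "R"
      regionName[k] <- sprintf("%s_region_%02d", hemi[k], k)
    }
    tab <- data.frame(label = seq_len(nParcels), region = regionName,
                      hemisphere = hemi, n_voxels = nvox,
                      stringsAsFactors = FALSE)
    new("AtlasPhantom", labels = lab,
        voxelSize = rep_len(voxelSize, 3L), labelTable = tab,
        seed = as.integer(seed))
  })
}

## smallest block count >= nParcels whose minimum block still holds minVox
chooseAxisSplit <- function(gridShape, nParcels, minVox) {
  best <- NULL
  bestScore <- Inf
  for (nx in seq_len(gridShape[1])) for (ny in seq_len(gridShape[2])) {
    needZ <- ceiling(nParcels / (nx * ny))
    for (nz in seq.int(needZ, gridShape[3])) {
      nb <- nx * ny * nz
      if (nb < nParcels) next
      minBlock <- prod(gridShape %/% c(nx, ny, nz))
      if (minBlock < minVox) next
      score <- nb + max(nx, ny, nz) / 100  # prefer few, balanced blocks
      if (score < bestScore) { bestScore <- score; best <- c(nx, ny, nz) }
      break  # larger nz only shrinks blocks
    }
  }
  best
}

axisSegments <- function(n, k) {
  cuts <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Draw cohort ground truth for a phantom
#'
#' Draws per-parcel population CVR from a lognormal distribution
#' (reactivity is positive and right-skewed), per-subject CVR as the parcel
#' value times a lognormal subject factor, and task amplitudes from the
#' linear coupling model
#' \code{task = intercept + slope * (cvrSubject * deltaPetco2) + N(0, subjectSd)}.
#' The breath-hold PSC surrogate of a parcel is \code{cvrSubject * deltaPetco2}.
#'
#' @param phantom an \linkS4class{AtlasPhantom}.
#' @param nSubjects cohort size (>= 1).
#' @param couplingSlope,couplingIntercept coupling model coefficients
#'   (\% per \% and \%).
#' @param cvrLogMean,cvrLogSd lognormal parameters of the per-parcel CVR in
#'   \%BOLD/mmHg (defaults: median 0.2 \%/mmHg, sdlog 0.25); \code{cvrLogSd}
#'   must be positive.
#' @param subjectSd residual task-amplitude sd (\%).
#' @param cvrSubjectSd sdlog of the per-subject CVR factor.
#' @param deltaPetco2 nominal hypercapnic end-tidal rise (mmHg).
#' @param lagChoices pool the per-subject hemodynamic delay is drawn from (s).
#' @param noiseSd default temporal noise scale for simulated runs
#'   (\% of baseline).
#' @param seed integer seed.
#' @return A \linkS4class{GroundTruth}.
#' @export
drawGroundTruth <- function(phantom, nSubjects,
                            couplingSlope = 0.5, couplingIntercept = 0.2,
                            cvrLogMean = log(0.2), cvrLogSd = 0.25,
                            subjectSd = 0.3, cvrSubjectSd = 0.3,
                            deltaPetco2 = 9.81, lagChoices = c(0, 2, 4, 6),
                            noiseSd = 0.5, seed = 1) {
  stopifnot(is(phantom, "AtlasPhantom"))
  if (nSubjects < 1) stop("'nSubjects' must be >= 1")
  if (!is.finite(cvrLogSd) || cvrLogSd <= 0)
    stop("'cvrLogSd' must be positive (degenerate lognormal draw)")
  if (cvrSubjectSd < 0) stop("'cvrSubjectSd' must be >= 0")
  R <- nParcels(phantom)
  withSeed(seed, {
    cvr <- stats::rlnorm(R, cvrLogMean, cvrLogSd)
    subjFac <- matrix(stats::rlnorm(R * nSubjects, 0, cvrSubjectSd),
                      R, nSubjects)
    cvrSubject <- cvr * subjFac
    bhPsc <- cvrSubject * deltaPetco2
    task <- couplingIntercept + couplingSlope * bhPsc +
      matrix(stats::rnorm(R * nSubjects, 0, subjectSd), R, nSubjects)
    pool <- rep_len(lagChoices, max(nSubjects, length(lagChoices)))
    lag <- pool[sample.int(length(pool), nSubjects)]
    new("GroundTruth", cvrTrue = cvr, cvrSubject = cvrSubject,
        taskAmpTrue = task, couplingSlope = couplingSlope,
        couplingIntercept = couplingIntercept, subjectLag = lag,
        subjectSd = subjectSd, deltaPetco2 = deltaPetco2,
        noiseSd = noiseSd, seed = as.integer(seed))
  })
}
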
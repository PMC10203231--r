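## Shared fixtures, built once per test run.

.fix <- new.env()

## 8-parcel phantom on a small grid (100 voxels/parcel)
fixPhantom <- function() {
  if (is.null(.fix$phantom))
    .fix$phantom <- generatePhantom(8, c(10, 10, 8), seed = 7)
  .fix$phantom
}

## 6-subject cohort with lags spanning the staggered grid
fixTruth <- function() {
  if (is.null(.fix$truth))
    .fix$truth <- drawGroundTruth(fixPhantom(), 6,
                                  lagChoices = c(0, 2, 4, 6, 8, 10),
                                  seed = 2)
  .fix$truth
}

## extract per-parcel means of a 3D map over the phantom labels
parcelMeans <- function(arr, phantom) {
  vapply(seq_len(nParcels(phantom)),
         function(k) mean(arr[phantom@labels == k], na.rm = TRUE),
         numeric(1))
}

## build a BoldRun directly from a voxel x time matrix (toy GLM problems)
toyRun <- function(Y, tr = 2) {
  nvox <- nrow(Y)
  d <- c(nvox, 1L, 1L)
  dat <- array(0, c(d, ncol(Y)))
  for (v in seq_len(ncol(Y))) dat[, 1, 1, v] <- Y[, v]
  new("BoldRun", data = dat, tr = tr, mask = array(TRUE, d),
      affine = diag(4), meta = list())
}

## brute-force OLS oracle: normal equations by explicit inversion
olsOracle <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y
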
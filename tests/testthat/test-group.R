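mkImgs <- function(n, d, f) lapply(seq_len(n), function(s) f(s))

test_that("group one-sample t matches a per-voxel textbook oracle", {
  d <- c(5, 4, 3); n <- 8
  withr::with_seed(11, {
    imgs <- mkImgs(n, d, function(s) array(rnorm(prod(d), 0.3), d))
    st <- groupTTest(imgs)
    arr <- simplify2array(imgs)
    for (v in sample(prod(d), 10)) {
      ijk <- arrayInd(v, d)
      y <- arr[ijk[1], ijk[2], ijk[3], ]
      tt <- t.test(y, alternative = "greater")
      expect_equal(st@t[ijk[1], ijk[2], ijk[3]], unname(tt$statistic),
                   tolerance = 1e-10)
      expect_equal(st@p[ijk[1], ijk[2], ijk[3]], tt$p.value,
                   tolerance = 1e-10)
    }
    expect_equal(st@dof, n - 1)
  })
})

test_that("degenerate voxels are masked, and t scales as truth*sqrt(n)/sigma", {
  d <- c(4, 4, 2); n <- 6
  ## identical nonzero images: zero between-subject variance
  same <- mkImgs(n, d, function(s) array(2, d))
  expect_message(st <- groupTTest(same), "zero-variance")
  expect_equal(sum(st@mask), 0)
  ## all-zero images: no suprathreshold voxels anywhere
  zero <- mkImgs(n, d, function(s) array(0, d))
  st0 <- suppressMessages(groupTTest(zero))
  expect_equal(sum(!is.na(st0@p) & st0@p < 0.05), 0)
  ## truth + N(0, sigma): mean t ~ truth*sqrt(n)/sigma
  truth <- 1; sigma <- 0.5; n2 <- 20
  withr::with_seed(12, {
    imgs <- mkImgs(n2, d, function(s)
      array(truth + rnorm(prod(d), 0, sigma), d))
    stn <- groupTTest(imgs)
    expect_equal(mean(stn@t), truth * sqrt(n2) / sigma, tolerance = 0.15)
  })
})

test_that("a constant covariate changes only the degrees of freedom", {
  d <- c(4, 3, 2); n <- 10
  withr::with_seed(13, {
    imgs <- mkImgs(n, d, function(s) array(rnorm(prod(d), 0.5), d))
    covs <- mkImgs(n, d, function(s) array(7, d))  # same for all subjects
    unc <- groupTTest(imgs)
    cor <- voxelwiseCovariateCorrection(imgs, covs)
    expect_equal(attr(cor, "fallbackVoxels"), prod(d))
    ## fallback voxels reproduce the uncorrected statistic exactly
    expect_equal(cor@t, unc@t, tolerance = 1e-12)
  })
})

test_that("covariate-explained variance raises the peak t", {
  ph <- generatePhantom(4, c(6, 6, 4), seed = 3)
  lab <- ph@labels; n <- 15
  wins <- 0; nRep <- 20
  for (r in seq_len(nRep)) {
    tru <- drawGroundTruth(ph, n, seed = 700 + r)
    imgs <- lapply(1:n, function(s) {
      a <- array(NA_real_, dim(lab))
      a[lab > 0] <- tru@taskAmpTrue[lab[lab > 0], s]
      a })
    covs <- lapply(1:n, function(s) {
      a <- array(NA_real_, dim(lab))
      a[lab > 0] <- tru@cvrSubject[lab[lab > 0], s] * tru@deltaPetco2
      a })
    unc <- groupTTest(imgs, mask = lab > 0)
    cor <- voxelwiseCovariateCorrection(imgs, covs, mask = lab > 0)
    wins <- wins + (max(cor@t, na.rm = TRUE) > max(unc@t, na.rm = TRUE))
    expect_equal(cor@dof, n - 2)
  }
  expect_gte(wins / nRep, 0.95)
})

test_that("an uninformative covariate barely changes suprathreshold counts", {
  d <- c(6, 6, 4); n <- 18
  withr::with_seed(14, {
    rel <- replicate(25, {
      imgs <- mkImgs(n, d, function(s) array(0.8 + rnorm(prod(d), 0, 1), d))
      covs <- mkImgs(n, d, function(s) array(rnorm(prod(d)), d))
      unc <- groupTTest(imgs)
      cor <- voxelwiseCovariateCorrection(imgs, covs)
      cu <- sum(unc@p < 0.01, na.rm = TRUE)
      cc <- sum(cor@p < 0.01, na.rm = TRUE)
      (cc - cu) / max(cu, 1)
    })
    expect_lt(abs(mean(rel)), 0.05)
  })
})

test_that("the correction benefit grows with covariate-amplitude coupling", {
  d <- c(5, 5, 3); n <- 16
  meanDelta <- vapply(c(0, 0.6, 0.98), function(rho) {
    withr::with_seed(round(100 * rho) + 21, {
      mean(replicate(15, {
        amp <- rnorm(n, 1, 0.5)
        covv <- rho * amp + sqrt(1 - rho^2) * rnorm(n, 0, 0.5)
        imgs <- lapply(seq_len(n), function(s)
          array(amp[s] + rnorm(prod(d), 0, 0.3), d))
        covs <- lapply(seq_len(n), function(s) array(covv[s], d) +
                         array(rnorm(prod(d), 0, 0.01), d))
        unc <- groupTTest(imgs)
        cor <- voxelwiseCovariateCorrection(imgs, covs)
        max(cor@t, na.rm = TRUE) - max(unc@t, na.rm = TRUE)
      }))
    })
  }, numeric(1))
  expect_true(all(diff(meanDelta) > 0))
})

test_that("ROI covariate correction works region-wise", {
  ph <- generatePhantom(4, c(6, 6, 4), seed = 3)
  lab <- ph@labels; n <- 12
  withr::with_seed(15, {
    amp <- rnorm(n, 1, 0.4)
    imgs <- lapply(1:n, function(s) {
      a <- array(NA_real_, dim(lab))
      a[lab > 0] <- amp[s] + rnorm(sum(lab > 0), 0, 0.2)
      a })
    ## true amplitude as the scalar covariate for regions 1 and 2 only
    rv <- cbind(`1` = amp, `2` = amp)
    cor <- roiCovariateCorrection(imgs, rv, ph)
    expect_true(all(is.na(cor@t[lab == 3])))  # absent region absent
    expect_equal(cor@dof, n - 2)
    unc <- groupTTest(imgs, mask = lab == 1)
    expect_gt(max(cor@t[lab == 1], na.rm = TRUE),
              max(unc@t[lab == 1], na.rm = TRUE))
    ## constant scalar covariate: masked uncorrected analysis up to dof
    rvc <- cbind(`1` = rep(5, n))
    corc <- roiCovariateCorrection(imgs, rvc, ph)
    expect_equal(corc@t[lab == 1], unc@t[lab == 1], tolerance = 1e-12)
  })
})

test_that("sensitivity comparison reports counts, peaks and deltas", {
  d <- c(6, 6, 6)
  withr::with_seed(16, tv <- array(rnorm(prod(d), 2), d))
  pv <- pt(tv, df = 10, lower.tail = FALSE)
  mk <- function(t, p) new("StatMap", t = t, p = p, contrast = 1,
                           dof = 10, mask = array(TRUE, d))
  a <- mk(tv, pv)
  sens0 <- compareSensitivity(list(uncorrected = a, other = a),
                              voxelP = 0.01)
  expect_equal(sens0$delta_voxels$other, 0)
  expect_equal(sens0$delta_peak_t$other, 0)
  b <- mk(tv + 1, pv)  # p unchanged, t shifted
  sens1 <- compareSensitivity(list(uncorrected = a, plus = b),
                              voxelP = 0.01)
  expect_equal(sens1$delta_peak_t$plus, 1)
  ## counts match direct enumeration
  expect_equal(sens1$n_suprathreshold$uncorrected, sum(pv < 0.01))
  expect_error(compareSensitivity(list(uncorrected = a), voxelP = 1.2),
               "voxelP")
})

test_that("permutation cluster null yields a sane critical extent", {
  d <- c(6, 6, 4); n <- 10
  withr::with_seed(17, {
    imgs <- mkImgs(n, d, function(s) array(rnorm(prod(d)), d))
    pn <- permutationClusterNull(imgs, clusterP = 0.01, nPerm = 100,
                                 seed = 3)
    expect_length(pn$null_max_extents, 100)
    expect_gte(pn$critical_extent, 1)
    ## same seed reproduces the null exactly
    pn2 <- permutationClusterNull(imgs, clusterP = 0.01, nPerm = 100,
                                  seed = 3)
    expect_identical(pn$null_max_extents, pn2$null_max_extents)
  })
})

test_that("connected components label 6-neighbourhoods correctly", {
  m <- array(FALSE, c(4, 4, 2))
  m[1:2, 1, 1] <- TRUE          # cluster of 2
  m[4, 4, 2] <- TRUE            # isolated voxel
  m[1, 4, 1] <- TRUE; m[1, 4, 2] <- TRUE  # cluster of 2 across z
  lab <- cvrcoupling:::connectedComponents(m)
  expect_equal(max(lab), 3L)
  expect_equal(sort(tabulate(lab[lab > 0])), c(1L, 2L, 2L))
  ## diagonal voxels are NOT connected
  m2 <- array(FALSE, c(3, 3, 1)); m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE
  expect_equal(max(cvrcoupling:::connectedComponents(m2)), 2L)
})
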
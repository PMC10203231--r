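mkMap <- function(arr) new("PscMap", psc = arr, contrast = 1,
                           baseline = array(1000, dim(arr)),
                           mask = !is.na(arr))

test_that("region sampling averages the joint-significant intersection", {
  ## hand-built 3-region toy with known voxel values
  lab <- array(0L, c(4, 3, 1))
  lab[1:2, 1, 1] <- 1L; lab[3:4, 1, 1] <- 2L; lab[1:4, 2, 1] <- 3L
  tab <- data.frame(label = 1:3, region = paste0("r", 1:3),
                    hemisphere = c("L", "R", "L"), n_voxels = c(2, 2, 4))
  atlas <- new("AtlasPhantom", labels = lab, voxelSize = rep(3, 3),
               labelTable = tab, seed = 1L)
  ## bypass the >= 20 voxel generation rule for this toy
  attr(atlas, "toy") <- TRUE
  task <- array(NA_real_, dim(lab)); cvr <- array(NA_real_, dim(lab))
  task[1:2, 1, 1] <- c(1.0, 2.0); cvr[1:2, 1, 1] <- c(0.1, 0.3)
  task[3:4, 1, 1] <- c(4.0, 6.0); cvr[3, 1, 1] <- 0.2   # voxel 4 fails cvr
  task[1:4, 2, 1] <- 1.7; cvr[1:4, 2, 1] <- 0.5          # constant region
  s <- extractRoiSamples(mkMap(task), mkMap(cvr), atlas, "s1")
  expect_equal(s$task_psc[s$roi == 1], mean(c(1, 2)))
  expect_equal(s$cvr_value[s$roi == 1], mean(c(0.1, 0.3)))
  expect_equal(s$task_psc[s$roi == 2], 4.0)   # only the joint voxel
  expect_equal(s$n_voxels[s$roi == 2], 1L)
  expect_equal(s$task_psc[s$roi == 3], 1.7)
  ## empty intersection: region absent
  cvr2 <- cvr; cvr2[1:2, 1, 1] <- NA_real_
  s2 <- extractRoiSamples(mkMap(task), mkMap(cvr2), atlas, "s1")
  expect_false(1 %in% s2$roi)
  ## grid mismatch is an error
  bad <- array(NA_real_, c(2, 2, 1))
  expect_error(extractRoiSamples(mkMap(bad), mkMap(cvr), atlas, "s1"),
               "grids do not match")
})

test_that("MAD filter follows its hand-computed oracle in both conventions", {
  x <- c(1, 1, 1, 1, 100)
  ## mean-centred: mean 20.8, deviations (19.8 x4, 79.2),
  ## MAD = 158.4/5 = 31.68, 3*MAD = 95.04 > 79.2 -> nothing removed
  fm <- madFilter(x, k = 3, center = "mean")
  expect_length(fm$excluded, 0)
  ## median-centred: median 1, deviations (0 x4, 99),
  ## MAD = 99/5 = 19.8, 3*MAD = 59.4 < 99 -> 100 removed
  fmed <- madFilter(x, k = 3, center = "median")
  expect_equal(fmed$excluded, 5L)
  expect_equal(fmed$retained, rep(1, 4))
  ## tight symmetric cluster: nothing removed
  expect_length(madFilter(c(9, 10, 11, 10, 9, 11), 3)$excluded, 0)
  ## k -> infinity is the identity
  expect_length(madFilter(x, k = 1e6)$excluded, 0)
  ## identical values: no removals
  expect_length(madFilter(rep(2, 5), 3)$excluded, 0)
  expect_error(madFilter(c(1, 2), 3), "at least 3")
})

test_that("SD pair filter removes gross outliers on either coordinate", {
  withr::with_seed(10, {
    df <- data.frame(task_psc = rnorm(20), cvr_value = rnorm(20))
    df$task_psc[7] <- df$task_psc[7] + 10 * sd(df$task_psc[-7])
    f <- sdFilter(df, k = 3)
    expect_true(7 %in% f$excluded)
    ## everything within 1 SD: identity
    tight <- data.frame(a = seq(-0.5, 0.5, length.out = 10),
                        b = seq(0.5, -0.5, length.out = 10))
    expect_length(sdFilter(tight, 3)$excluded, 0)
    ## mixed case against a direct z-score oracle
    df2 <- data.frame(a = rnorm(30), b = rnorm(30))
    df2$a[3] <- 8; df2$b[11] <- -9
    f2 <- sdFilter(df2, k = 3)
    zo <- function(x) abs(x - mean(x)) / sd(x) > 3
    expect_setequal(f2$excluded, which(zo(df2$a) | zo(df2$b)))
    ## zero variance coordinate removes nothing on that coordinate
    df3 <- data.frame(a = rep(1, 10), b = rnorm(10))
    expect_length(sdFilter(df3, 3)$excluded, 0)
  })
})

mkSamples <- function(truth, deltaP = truth@deltaPetco2) {
  do.call(rbind, lapply(seq_len(ncol(truth@cvrSubject)), function(s)
    data.frame(subject = as.character(s),
               roi = seq_len(nrow(truth@cvrSubject)),
               task_psc = truth@taskAmpTrue[, s],
               cvr_value = truth@cvrSubject[, s] * deltaP,
               n_voxels = 50L)))
}

test_that("regions below the minimum-subjects rule are excluded", {
  tru <- drawGroundTruth(fixPhantom(), 12, seed = 6)
  samples <- mkSamples(tru)
  ## region 2 observed in only 9 subjects
  samples <- samples[!(samples$roi == 2 &
                         samples$subject %in% as.character(1:3)), ]
  res <- roiRegressions(samples, minN = 10)
  expect_false(2 %in% res$roi)
  expect_true(all(setdiff(1:8, 2) %in% res$roi))
  expect_true(all(res$n >= 10))
  expect_error(roiRegressions(samples, minN = 2), "minN")
})

test_that("noiseless coupling gives perfect regressions everywhere", {
  tru <- drawGroundTruth(fixPhantom(), 15, subjectSd = 0, seed = 7)
  res <- suppressWarnings(roiRegressions(mkSamples(tru), minN = 10))
  expect_equal(nrow(res), 8)
  expect_true(all(res$r2 > 1 - 1e-10))
  expect_true(all(res$fdr_significant))
  expect_equal(res$slope, rep(0.5, 8), tolerance = 1e-8)
})

test_that("FDR flags match a brute-force step-up enumeration", {
  tru <- drawGroundTruth(fixPhantom(), 20, subjectSd = 1.5, seed = 8)
  res <- roiRegressions(mkSamples(tru), minN = 10, q = 0.05)
  ## independent step-up oracle by enumeration over sorted p-values
  m <- nrow(res)
  ord <- order(res$p)
  passes <- which(res$p[ord] <= seq_len(m) / m * 0.05)
  rejected <- if (length(passes)) ord[seq_len(max(passes))] else integer(0)
  expect_setequal(which(res$fdr_significant), rejected)
})

test_that("summary percentages use one-decimal convention", {
  mkRes <- function(nSig, nTot) {
    data.frame(roi = seq_len(nTot), slope = 0.5, intercept = 0.2,
               r2 = 0.3, p = c(rep(0.001, nSig), rep(0.9, nTot - nSig)),
               n = 20, excluded_outliers = 0, slope_lo = 0.3,
               slope_hi = 0.7,
               p_fdr = c(rep(0.01, nSig), rep(0.9, nTot - nSig)),
               fdr_significant = c(rep(TRUE, nSig),
                                   rep(FALSE, nTot - nSig)))
  }
  expect_equal(summarizeRoi(mkRes(25, 34))$pct_significant, 73.5)
  expect_equal(summarizeRoi(mkRes(11, 24))$pct_significant, 45.8)
  expect_equal(summarizeRoi(mkRes(0, 12))$pct_significant, 0.0)
  s <- summarizeRoi(mkRes(25, 34), topK = 5)
  expect_equal(nrow(s$top), 5)
  expect_equal(nrow(s$r2_export), 34)
})

test_that("null coupling keeps the significant fraction near the FDR level", {
  ph <- fixPhantom()
  fracs <- vapply(1:40, function(r) {
    tru <- drawGroundTruth(ph, 15, couplingSlope = 0, seed = 400 + r)
    res <- roiRegressions(mkSamples(tru), minN = 10)
    mean(res$fdr_significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) / sqrt(length(fracs)))
})

test_that("voxel selection preserves the sign of a strong coupling", {
  ## high-SNR end-to-end: restricting to significant voxels must not flip
  ## a true positive slope
  ph <- generatePhantom(4, c(8, 8, 4), seed = 5)
  tru <- drawGroundTruth(ph, 12, subjectSd = 0.1, seed = 6)
  bh <- breathHoldParadigm()
  tp <- eventTaskParadigm(nEvents = 25, tr = 2, seed = 7)
  samples <- do.call(rbind, lapply(1:12, function(s) {
    rb <- simulateRun(ph, tru, bh, s, noiseSd = 0.5, seed = 20 + s)
    rt <- simulateRun(ph, tru, tp, s, noiseSd = 0.5, seed = 50 + s)
    fb <- fitBreathholdCvr(rb, bh)
    ft <- fitTaskGlm(rt, tp)
    bThr <- thresholdMap(fb$stat, fb$psc, 0.001)
    extractRoiSamples(ft$thresholded, bThr, ph, s)
  }))
  res <- roiRegressions(samples, minN = 10)
  expect_gt(nrow(res), 0)
  expect_true(all(res$slope > 0))
})
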
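test_that("GLM matches the brute-force normal-equation oracle", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(8:20, 1); p <- sample(2:5, 1)
      X <- cbind(constant = 1,
                 matrix(rnorm(n * (p - 1)), n,
                        dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
      Y <- matrix(rnorm(3 * n), 3, n)
      des <- new("DesignMatrix", values = X, tr = 2,
                 peakHeights = setNames(rep(NA_real_, p), colnames(X)))
      fit <- fitGlm(toyRun(Y), des)
      for (v in 1:3) {
        expect_equal(unname(fit@betas[v, ]),
                     unname(drop(olsOracle(X, Y[v, ]))),
                     tolerance = 1e-10)
      }
      expect_equal(fit@dof, n - p)
    }
  })
})

test_that("data in the design span is fitted exactly", {
  withr::with_seed(2, {
    X <- cbind(constant = 1, x1 = rnorm(12), x2 = rnorm(12))
    b <- c(3, -1.5, 0.25)
    Y <- rbind(drop(X %*% b))
    des <- new("DesignMatrix", values = X, tr = 2,
               peakHeights = c(constant = NA_real_, x1 = NA_real_,
                               x2 = NA_real_))
    fit <- fitGlm(toyRun(Y), des)
    expect_equal(unname(fit@betas[1, ]), b, tolerance = 1e-10)
    expect_lt(fit@sigma2[1], 1e-20)
  })
})

test_that("orthonormal designs give inner-product betas", {
  n <- 16
  Q <- qr.Q(qr(cbind(rep(1, n), sin(1:n), cos(1:n))))
  colnames(Q) <- c("constant", "s", "c")
  des <- new("DesignMatrix", values = Q, tr = 2,
             peakHeights = c(constant = NA_real_, s = NA_real_,
                             c = NA_real_))
  withr::with_seed(3, Y <- matrix(rnorm(2 * n), 2, n))
  fit <- fitGlm(toyRun(Y), des)
  for (v in 1:2)
    expect_equal(unname(fit@betas[v, ]), unname(drop(t(Q) %*% Y[v, ])),
                 tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the dependent columns", {
  X <- cbind(constant = 1, a = 1:10, b = 2 * (1:10))
  expect_error(new("DesignMatrix", values = X, tr = 2,
                   peakHeights = c(constant = NA_real_, a = NA_real_,
                                   b = NA_real_)),
               "rank deficient.*b")
})

test_that("contrast t matches the textbook formula and its invariances", {
  withr::with_seed(4, {
    n <- 15
    X <- cbind(constant = 1, x = rnorm(n))
    y <- 2 + 0.8 * X[, 2] + rnorm(n, 0, 0.5)
    des <- new("DesignMatrix", values = X, tr = 2,
               peakHeights = c(constant = NA_real_, x = NA_real_))
    fit <- fitGlm(toyRun(rbind(y)), des)
    st <- contrastT(fit, c(0, 1))
    ## scalar oracle
    b <- drop(olsOracle(X, y))
    res <- y - X %*% b
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(st@t[1, 1, 1], unname(b[2] / se), tolerance = 1e-12)
    expect_equal(st@p[1, 1, 1], unname(pt(b[2] / se, n - 2, lower.tail = FALSE)),
                 tolerance = 1e-12)
    ## zero contrast
    st0 <- contrastT(fit, c(0, 0))
    expect_equal(st0@t[1, 1, 1], 0)
    ## doubling data and design leaves t unchanged
    des2 <- new("DesignMatrix", values = 2 * X, tr = 2,
                peakHeights = c(constant = NA_real_, x = NA_real_))
    fit2 <- fitGlm(toyRun(rbind(2 * y)), des2)
    st2 <- contrastT(fit2, c(0, 1))
    expect_equal(st2@t[1, 1, 1], st@t[1, 1, 1], tolerance = 1e-10)
  })
})

test_that("p-values are uniform under pure noise", {
  nvox <- 5000; n <- 60
  h <- canonicalHrf(0.125)
  reg <- buildRegressor(seq(5, 100, by = 12), h, n, 2, isSeries = FALSE)
  des <- designMatrix(list(reg), n, 2)
  withr::with_seed(5, Y <- matrix(rnorm(nvox * n), nvox, n))
  fit <- fitGlm(toyRun(Y), des)
  st <- contrastT(fit, "task")
  ks <- suppressWarnings(ks.test(as.numeric(st@p[!is.na(st@p)]), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("percent signal change follows the peak-height convention", {
  ## baseline 100, effect 1.5 at unit peak height -> psc = 1.5
  n <- 30
  x <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  X <- cbind(constant = 1, task = x)
  y <- 100 + 1.5 * x
  des <- new("DesignMatrix", values = X, tr = 2,
             peakHeights = c(constant = NA_real_, task = 1))
  fit <- fitGlm(toyRun(rbind(y)), des)
  psc <- percentSignalChange(fit, "task")
  expect_equal(psc@psc[1, 1, 1], 1.5, tolerance = 1e-10)
  expect_equal(psc@baseline[1, 1, 1], 100, tolerance = 1e-10)
  ## raw scaling ignores peak height
  pscRaw <- percentSignalChange(fit, "task", scaling = "raw")
  expect_equal(pscRaw@psc[1, 1, 1], 1.5, tolerance = 1e-10)
})

test_that("injected amplitudes are recovered across kernels and paradigms", {
  ph <- fixPhantom(); tru <- fixTruth()
  ## breath-hold forward model under each generating kernel, fitted with
  ## the matched kernel
  bh <- breathHoldParadigm()
  dt <- 2 / 16
  kernels <- list(rrf = respiratoryResponseFunction(dt),
                  hrf = canonicalHrf(dt))
  for (kern in c("rrf", "hrf")) {
    run <- simulateRun(ph, tru, bh, 2, noiseSd = 0, seed = 1,
                       forceKernel = kern)
    sf <- staggeredFit(run, bh, kernels[[kern]])
    psc <- percentSignalChange(sf$fit, "breath_hold")
    inj <- tru@cvrSubject[, 2] * tru@deltaPetco2
    est <- parcelMeans(psc@psc, ph)
    expect_equal(est, inj, tolerance = 0.01)
  }
  ## event task
  tp <- eventTaskParadigm(nEvents = 30, tr = 2, seed = 4)
  runT <- simulateRun(ph, tru, tp, 2, noiseSd = 0, seed = 1)
  resT <- fitTaskGlm(runT, tp)
  expect_equal(parcelMeans(resT$psc@psc, ph), tru@taskAmpTrue[, 2],
               tolerance = 0.01)
})

test_that("nuisance contrasts on null data stay near zero", {
  withr::with_seed(6, {
    n <- 40
    X <- cbind(constant = 1, task = rnorm(n))
    Y <- matrix(100 + rnorm(5 * n), 5, n)
    des <- new("DesignMatrix", values = X, tr = 2,
               peakHeights = c(constant = NA_real_, task = 1))
    fit <- fitGlm(toyRun(Y), des)
    psc <- percentSignalChange(fit, "task")
    st <- contrastT(fit, "task", sided = "two")
    vals <- psc@psc[!is.na(psc@psc)]
    expect_true(all(abs(vals) < 5))  # fractions of a percent around zero
    expect_gt(min(st@p, na.rm = TRUE), 1e-4)
  })
})

test_that("thresholding keeps true actives and rejects nulls", {
  ## high-SNR simulation with 30% truly active voxels
  withr::with_seed(7, {
    nAct <- 600; nNull <- 1400; n <- 60
    h <- canonicalHrf(0.125)
    reg <- buildRegressor(seq(5, 100, by = 15), h, n, 2, isSeries = FALSE)
    sig <- 3 * reg@samples / reg@peakHeight
    Y <- rbind(
      matrix(rep(100 * (1 + 0.05 * sig), nAct), nAct, n, byrow = TRUE),
      matrix(100, nNull, n)) + matrix(rnorm((nAct + nNull) * n), ncol = n)
    des <- designMatrix(list(reg), n, 2)
    fit <- fitGlm(toyRun(Y), des)
    st <- contrastT(fit, "task")
    psc <- percentSignalChange(fit, "task")
    thr <- thresholdMap(st, psc, alpha = 0.001)
    kept <- !is.na(thr@psc)
    expect_gte(mean(kept[seq_len(nAct)]), 0.95)
    expect_lte(mean(kept[nAct + seq_len(nNull)]), 0.005)
    ## boundary behaviour of alpha
    expect_equal(sum(!is.na(thresholdMap(st, psc, alpha = 1)@psc)),
                 sum(fit@mask))
    expect_equal(sum(!is.na(thresholdMap(st, psc, alpha = 1e-300)@psc)),
                 sum(!is.na(st@p) & st@p < 1e-300))
    expect_error(thresholdMap(st, psc, alpha = 0), "alpha")
  })
})
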
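#' @include AllClasses.R kernels.R
NULL

#' Assemble a design matrix
#'
#' Binds task regressors with the standard nuisance set: a constant, a
#' drift basis (linear trend by default, or a cosine high-pass set with a
#' 128 s default cutoff), and optional motion-parameter columns.
#'
#' @param regressors list of \linkS4class{Regressor} objects (may be empty).
#' @param nVolumes number of volumes.
#' @param tr repetition time (s).
#' @param motion optional volumes x 6 motion-parameter matrix.
#' @param drift \code{"linear"}, \code{"cosine"} or \code{"none"}.
#' @param highpass cosine high-pass cutoff (s), used when
#'   \code{drift = "cosine"}.
#' @return A \linkS4class{DesignMatrix}. Rank deficiency is an error naming
#'   the dependent columns.
#' @export
designMatrix <- function(regressors = list(), nVolumes, tr, motion = NULL,
                         drift = c("linear", "cosine", "none"),
                         highpass = 128) {
  drift <- match.arg(drift)
  cols <- list(constant = rep(1, nVolumes))
  ph <- c(constant = NA_real_)
  for (r in regressors) {
    stopifnot(is(r, "Regressor"))
    if (length(r@samples) != nVolumes)
      stop(sprintf("regressor '%s' has %d samples but the run has %d volumes",
                   r@name, length(r@samples), nVolumes))
    cols[[r@name]] <- r@samples
    ph[r@name] <- r@peakHeight
  }
  tIdx <- seq_len(nVolumes) - 1
  if (drift == "linear") {
    cols[["drift_linear"]] <- scale(tIdx, scale = FALSE)[, 1]
    ph["drift_linear"] <- NA_real_
  } else if (drift == "cosine") {
    K <- max(1L, floor(2 * nVolumes * tr / highpass))
    for (k in seq_len(K)) {
      nm <- sprintf("drift_cos%02d", k)
      cols[[nm]] <- cos(pi * k * (tIdx + 0.5) / nVolumes)
      ph[nm] <- NA_real_
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nVolumes) stop("motion rows must match volumes")
    cn <- colnames(motion) %||% paste0("motion_", seq_len(ncol(motion)))
    for (j in seq_len(ncol(motion))) {
      cols[[cn[j]]] <- motion[, j]
      ph[cn[j]] <- NA_real_
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  new("DesignMatrix", values = X, tr = tr, peakHeights = ph)
}

#' Fit the mass-univariate GLM
#'
#' Ordinary least squares per voxel via a QR factorization of the design.
#' Voxels whose time series is exactly constant (synthetic background,
#' degenerate coverage) are dropped from the mask with a logged count
#' rather than producing non-finite statistics.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param design a \linkS4class{DesignMatrix} with rows matching the run's
#'   volumes.
#' @return A \linkS4class{GlmResult}.
#' @export
fitGlm <- function(run, design) {
  stopifnot(is(run, "BoldRun"), is(design, "DesignMatrix"))
  X <- design@values
  if (nrow(X) != nVolumes(run))
    stop(sprintf("design has %d rows but the run has %d volumes",
                 nrow(X), nVolumes(run)))
  mask <- run@mask
  if (!any(mask)) stop("mask is empty")
  d <- dim(run@data)
  Y <- matrix(run@data[rep(mask, d[4])], nrow = sum(mask))
  constant <- matrixStats_rowVars(Y) <= 0
  if (any(constant)) {
    message(sprintf("fitGlm: dropping %d constant voxel(s) from the mask",
                    sum(constant)))
    mask[which(mask)[constant]] <- FALSE
    Y <- Y[!constant, , drop = FALSE]
    if (!any(mask)) stop("mask is empty after dropping constant voxels")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop(paste0("design matrix is rank deficient; dependent columns: ",
                paste(dependentColumns(X), collapse = ", ")))
  tY <- t(Y)
  betas <- qr.coef(qrX, tY)
  res <- tY - X %*% betas
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / dof
  new("GlmResult", betas = t(betas), sigma2 = as.numeric(sigma2),
      dof = dof, design = design, mask = mask, dims = d[1:3])
}

matrixStats_rowVars <- function(Y) {
  mu <- rowMeans(Y)
  rowSums((Y - mu)^2) / (ncol(Y) - 1)
}

#' Contrast t map
#'
#' \code{t = w'b / sqrt(sigma2 * w' (X'X)^-1 w)} per voxel, with one-sided
#' upper-tail p-values by default (activation-greater-than-baseline
#' contrasts). Voxels fitted exactly (zero residual variance) receive
#' infinite |t| and a p of 0 or 1 by the sign of the contrast estimate
#' rather than propagating NaN.
#'
#' @param result a \linkS4class{GlmResult}.
#' @param weights contrast vector (length = design columns) or a single
#'   design column name.
#' @param sided \code{"one"} (upper tail) or \code{"two"}.
#' @return A \linkS4class{StatMap}.
#' @export
contrastT <- function(result, weights, sided = c("one", "two")) {
  sided <- match.arg(sided)
  X <- result@design@values
  w <- resolveWeights(weights, X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  cw <- drop(t(w) %*% XtXinv %*% w)
  eff <- drop(result@betas %*% w)
  se <- sqrt(result@sigma2 * cw)
  tval <- ifelse(se > 0, eff / se, sign(eff) * Inf)
  tval[se == 0 & eff == 0] <- 0
  p <- stats::pt(tval, df = result@dof, lower.tail = FALSE)
  if (sided == "two") p <- 2 * stats::pt(abs(tval), result@dof,
                                         lower.tail = FALSE)
  tArr <- array(NA_real_, result@dims); tArr[result@mask] <- tval
  pArr <- array(NA_real_, result@dims); pArr[result@mask] <- p
  new("StatMap", t = tArr, p = pArr, contrast = w, dof = result@dof,
      mask = result@mask)
}

resolveWeights <- function(weights, X) {
  if (is.character(weights)) {
    w <- numeric(ncol(X))
    names(w) <- colnames(X)
    if (!all(weights %in% colnames(X)))
      stop("unknown design column in contrast: ",
           paste(setdiff(weights, colnames(X)), collapse = ", "))
    w[weights] <- 1
  } else {
    if (length(weights) != ncol(X))
      stop("contrast length must equal the number of design columns")
    w <- as.numeric(weights)
    names(w) <- colnames(X)
  }
  w
}

#' Percent-signal-change map
#'
#' Scales the contrast estimate to percent of baseline:
#' \code{psc = 100 * (w'b) * peakHeight / b_constant}, where
#' \code{peakHeight} is the maximum absolute amplitude of the weighted task
#' regressor at the convolution resolution (stored on each
#' \linkS4class{Regressor}) and \code{b_constant} the constant-column beta.
#' Voxels with non-positive baseline are masked out.
#'
#' @param result a \linkS4class{GlmResult}.
#' @param weights contrast vector or design column name(s) (weight 1 each).
#' @param scaling \code{"peak"} (default, peak-height scaling) or
#'   \code{"raw"} (plain beta ratio).
#' @return A \linkS4class{PscMap}.
#' @export
percentSignalChange <- function(result, weights, scaling = c("peak", "raw")) {
  scaling <- match.arg(scaling)
  X <- result@design@values
  w <- resolveWeights(weights, X)
  constIdx <- which(colnames(X) == "constant")
  b0 <- result@betas[, constIdx]
  eff <- drop(result@betas %*% w)
  ph <- 1
  if (scaling == "peak") {
    phs <- result@design@peakHeights
    active <- which(w != 0 & colnames(X) != "constant")
    if (length(active) == 1L && is.finite(phs[colnames(X)[active]])) {
      ph <- abs(w[active]) * phs[colnames(X)[active]]
    } else if (length(active) > 0L) {
      comb <- X[, active, drop = FALSE] %*% w[active]
      ph <- max(abs(comb))
    }
  }
  ok <- b0 > 0
  psc <- rep(NA_real_, length(eff))
  psc[ok] <- 100 * eff[ok] * ph / b0[ok]
  pArr <- array(NA_real_, result@dims); pArr[result@mask] <- psc
  bArr <- array(NA_real_, result@dims); bArr[result@mask] <- b0
  mask <- result@mask
  mask[result@mask][!ok] <- FALSE
  new("PscMap", psc = pArr, contrast = w, baseline = bArr, mask = mask)
}

#' Threshold a PSC map by voxel-wise significance
#'
#' Retains PSC values only where the statistic map's p-value is below
#' \code{alpha} (the voxel-selection criterion is p < 0.001 uncorrected by
#' convention); other voxels are set to NA.
#'
#' @param stat a \linkS4class{StatMap}.
#' @param psc a \linkS4class{PscMap} on the same grid.
#' @param alpha voxel threshold in (0, 1].
#' @return The thresholded \linkS4class{PscMap}; the retained voxel count
#'   is available as \code{attr(, "retained")}.
#' @export
thresholdMap <- function(stat, psc, alpha = 0.001) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]")
  stopifnot(identical(dim(stat@p), dim(psc@psc)))
  keep <- !is.na(stat@p) & stat@p < alpha & !is.na(psc@psc)
  out <- psc
  out@psc[!keep] <- NA_real_
  out@mask <- keep
  attr(out, "retained") <- sum(keep)
  out
}

#' Count significant voxels of a statistic map
#'
#' @param stat a \linkS4class{StatMap}.
#' @param alpha voxel p threshold.
#' @return integer count of in-mask voxels with p < alpha.
#' @export
countSignificant <- function(stat, alpha = 0.001) {
  sum(stat@p < alpha, na.rm = TRUE)
}

#' Spatially smooth a BOLD run
#'
#' Volume-wise separable Gaussian smoothing (the gas-challenge convention
#' uses a minimal 4 mm FWHM kernel; the breath-hold convention uses none).
#'
#' @param run a \linkS4class{BoldRun}.
#' @param fwhm full width at half maximum (mm).
#' @param voxelSize voxel size (mm); defaults to the affine diagonal.
#' @return The smoothed \linkS4class{BoldRun}.
#' @export
smoothRun <- function(run, fwhm = 4, voxelSize = NULL) {
  voxelSize <- voxelSize %||% abs(diag(run@affine)[1:3])
  d <- dim(run@data)
  out <- run@data
  for (v in seq_len(d[4]))
    out[, , , v] <- gaussianSmooth3d(run@data[, , , v], fwhm, voxelSize)
  run@data <- out
  run
}
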
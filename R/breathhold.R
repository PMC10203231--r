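#' @include AllClasses.R glm.R
NULL

#' Staggered-onset model selection for breath-hold runs
#'
#' Fits one GLM per candidate onset lag (the ramp input delayed by
#' 0, step, ..., maxLag seconds before convolution with the response
#' kernel) and records the number of significant voxels at the selection
#' threshold for each. The model with the most significant voxels wins;
#' ties go to the smallest lag. When no lag yields any significant voxel,
#' the best model is still returned and the report carries a warning flag.
#'
#' @param run a breath-hold \linkS4class{BoldRun}.
#' @param paradigm its \linkS4class{ParadigmSpec}.
#' @param kernel a \linkS4class{ResponseKernel} (respiratory by convention).
#' @param maxLag largest lag tested (s); default 12.
#' @param step lag increment (s); defaults to the run's TR.
#' @param alpha voxel selection threshold (one-sided p; default 0.001).
#' @param motion optional motion-parameter matrix for the nuisance set.
#' @param extendIntoRest ramp convention flag (see
#'   \code{\link{rampRegressor}}).
#' @return list with elements \code{fit} (the winning
#'   \linkS4class{GlmResult}), \code{stat} (its \linkS4class{StatMap}) and
#'   \code{report} (a \linkS4class{LagSearchReport}).
#' @export
staggeredFit <- function(run, paradigm, kernel, maxLag = 12, step = NULL,
                         alpha = 0.001, motion = NULL,
                         extendIntoRest = FALSE) {
  stopifnot(is(run, "BoldRun"), is(paradigm, "ParadigmSpec"))
  if (paradigm@kind != "breath_hold")
    stop("staggeredFit requires a breath_hold paradigm")
  step <- step %||% run@tr
  if (step <= 0) stop("'step' must be positive")
  if (maxLag < 0) stop("'maxLag' must be >= 0")
  lags <- seq(0, maxLag, by = step)
  dt <- kernel@dt
  ramp <- rampRegressor(paradigm, dt, extendIntoRest = extendIntoRest)
  nVol <- nVolumes(run)
  fits <- vector("list", length(lags))
  stats <- vector("list", length(lags))
  counts <- integer(length(lags))
  meanSigT <- rep(-Inf, length(lags))
  for (i in seq_along(lags)) {
    reg <- buildRegressor(ramp, kernel, nVol, run@tr, onsetShift = lags[i],
                          isSeries = TRUE, name = "breath_hold")
    des <- designMatrix(list(reg), nVol, run@tr, motion = motion)
    fit <- fitGlm(run, des)
    st <- contrastT(fit, "breath_hold")
    fits[[i]] <- fit
    stats[[i]] <- st
    counts[i] <- countSignificant(st, alpha)
    if (counts[i] > 0)
      meanSigT[i] <- mean(st@t[!is.na(st@p) & st@p < alpha])
  }
  ## most significant voxels wins; count ties (which arise when noise is
  ## too low to limit the count) go to the better-fitting model, and only
  ## exact ties in both fall back to the smallest lag
  best <- order(-counts, -meanSigT, lags)[1]
  report <- new("LagSearchReport", lagsTested = lags,
                sigVoxelCounts = counts, chosenLag = lags[best],
                chosenKernel = kernel@kind, fallbackUsed = FALSE,
                warning = max(counts) == 0L)
  if (report@warning)
    warning("no lag produced significant voxels; returning the first model")
  list(fit = fits[[best]], stat = stats[[best]], report = report)
}

#' Breath-hold CVR surrogate map with HRF fallback
#'
#' Runs the staggered-onset search with the respiratory response function;
#' if the winning model's significant-voxel count falls below
#' \code{fallbackThreshold} (too few voxels to support a region analysis),
#' the search is rerun with the canonical HRF and whichever kernel yields
#' more significant voxels is kept. Outputs the winner's percent-signal-
#' change and statistic maps plus the full search report.
#'
#' @param run a breath-hold \linkS4class{BoldRun}.
#' @param paradigm its \linkS4class{ParadigmSpec}.
#' @param maxLag,step,alpha,motion,extendIntoRest passed to
#'   \code{\link{staggeredFit}}.
#' @param fallbackThreshold minimum significant-voxel count for the
#'   respiratory kernel to be accepted (default 100).
#' @param kernelDt convolution resolution (s); defaults to tr/16.
#' @return list with \code{psc} (\linkS4class{PscMap}), \code{stat}
#'   (\linkS4class{StatMap}), \code{report} (\linkS4class{LagSearchReport})
#'   and \code{fit}.
#' @export
fitBreathholdCvr <- function(run, paradigm, maxLag = 12, step = NULL,
                             alpha = 0.001, motion = NULL,
                             fallbackThreshold = 100,
                             extendIntoRest = FALSE, kernelDt = NULL) {
  dt <- kernelDt %||% (run@tr / 16)
  rrf <- respiratoryResponseFunction(dt)
  res <- staggeredFit(run, paradigm, rrf, maxLag = maxLag, step = step,
                      alpha = alpha, motion = motion,
                      extendIntoRest = extendIntoRest)
  bestCount <- max(res$report@sigVoxelCounts)
  fallback <- FALSE
  if (bestCount < fallbackThreshold) {
    hrf <- canonicalHrf(dt)
    alt <- staggeredFit(run, paradigm, hrf, maxLag = maxLag, step = step,
                        alpha = alpha, motion = motion,
                        extendIntoRest = extendIntoRest)
    if (max(alt$report@sigVoxelCounts) > bestCount) {
      res <- alt
      fallback <- TRUE
    }
  }
  rep <- res$report
  rep@fallbackUsed <- fallback
  psc <- percentSignalChange(res$fit, "breath_hold")
  list(psc = psc, stat = res$stat, report = rep, fit = res$fit)
}

#' Fit an event-related task run
#'
#' Builds correct-trial task regressors (delta sticks at onset times
#' convolved with the canonical HRF), models incorrect trials as a
#' separate regressor of no interest, adds the standard nuisance set, and
#' returns the contrast PSC and statistic maps for the correct-trial
#' effect.
#'
#' @param run an event-task \linkS4class{BoldRun}.
#' @param paradigm its \linkS4class{ParadigmSpec}.
#' @param conditions optional character vector restricting the contrast to
#'   a subset of condition labels (matched as prefixes against the
#'   paradigm's condition strings); default all correct trials in one
#'   regressor.
#' @param motion optional motion matrix.
#' @param alpha voxel threshold for the returned thresholded map.
#' @param kernelDt convolution resolution (s); defaults to tr/16.
#' @return list with \code{psc}, \code{stat}, \code{thresholded}
#'   (PSC map at \code{alpha}) and \code{fit}.
#' @export
fitTaskGlm <- function(run, paradigm, conditions = NULL, motion = NULL,
                       alpha = 0.001, kernelDt = NULL) {
  stopifnot(paradigm@kind == "event_task")
  dt <- kernelDt %||% (run@tr / 16)
  hrf <- canonicalHrf(dt)
  nVol <- nVolumes(run)
  correct <- if (length(paradigm@correctness)) paradigm@correctness
             else rep(TRUE, length(paradigm@onsets))
  sel <- correct
  if (!is.null(conditions)) {
    hit <- Reduce(`|`, lapply(conditions, function(cd)
      startsWith(paradigm@conditions, cd)))
    sel <- sel & hit
  }
  if (!any(sel)) stop("no correct events match the requested conditions")
  regs <- list(buildRegressor(paradigm@onsets[sel], hrf, nVol, run@tr,
                              isSeries = FALSE, name = "task"))
  if (any(!correct))
    regs <- c(regs, list(buildRegressor(paradigm@onsets[!correct], hrf,
                                        nVol, run@tr, isSeries = FALSE,
                                        name = "incorrect")))
  des <- designMatrix(regs, nVol, run@tr, motion = motion)
  fit <- fitGlm(run, des)
  stat <- contrastT(fit, "task")
  psc <- percentSignalChange(fit, "task")
  list(psc = psc, stat = stat,
       thresholded = thresholdMap(stat, psc, alpha), fit = fit)
}

#' Fraction of subjects requiring the HRF fallback
#'
#' @param reports list of \linkS4class{LagSearchReport} objects (one per
#'   subject).
#' @return list with \code{n}, \code{n_fallback} and \code{pct} (percentage
#'   rounded to the nearest whole percent, the convention fallback rates
#'   are reported in).
#' @export
fallbackFraction <- function(reports) {
  fb <- vapply(reports, function(r) r@fallbackUsed, logical(1))
  list(n = length(fb), n_fallback = sum(fb),
       pct = round(100 * sum(fb) / length(fb)))
}
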
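#' @include AllClasses.R glm.R utils.R
NULL

#' Extract the end-tidal CO2 series from a capnograph trace
#'
#' Detects per-breath end-tidal peaks as local maxima with a minimum
#' separation of 2 s and a prominence of at least 2 mmHg, linearly
#' interpolates the peak values onto volume acquisition times, and
#' computes the pre-challenge baseline (mean end-tidal value over
#' \code{baselineWindow}) and the maximum end-tidal change
#' \code{max(resampled) - baseline}.
#'
#' @param trace a \linkS4class{RespiratoryTrace}.
#' @param tr repetition time of the matching run (s).
#' @param nVolumes number of volumes to resample onto.
#' @param baselineWindow numeric(2), seconds; window over which the
#'   baseline plateau is averaged (must lie before the challenge).
#' @param minSeparation,minProminence peak-detection rules (s, mmHg).
#' @return An \linkS4class{EndTidalSeries}. No detectable breaths is an
#'   error; a non-positive maximum change (failed challenge) warns.
#' @export
extractEndTidal <- function(trace, tr, nVolumes,
                            baselineWindow = c(30, 110),
                            minSeparation = 2, minProminence = 2) {
  stopifnot(is(trace, "RespiratoryTrace"))
  dt <- trace@time[2] - trace@time[1]
  if (utils::tail(trace@time, 1) + dt < nVolumes * tr - tr)
    stop("trace is shorter than the run it should cover")
  pk <- findProminentPeaks(trace@co2, minSeparation, minProminence, dt)
  if (!length(pk)) stop("no detectable breaths in the trace")
  bt <- trace@time[pk]
  pet <- trace@co2[pk]
  volTimes <- (seq_len(nVolumes) - 1) * tr
  resampled <- stats::approx(bt, pet, xout = volTimes, rule = 2)$y
  inBase <- bt >= baselineWindow[1] & bt <= baselineWindow[2]
  if (!any(inBase)) stop("no breaths inside the baseline window")
  baseline <- mean(pet[inBase])
  maxChange <- max(resampled) - baseline
  if (maxChange <= 0)
    warning("non-positive end-tidal change: the challenge appears to have failed")
  new("EndTidalSeries", breathTimes = bt, petco2 = pet,
      resampled = resampled, volTimes = volTimes, baseline = baseline,
      maxChange = maxChange)
}

#' Cross-correlation shift optimization
#'
#' Shifts the end-tidal series forward in TR steps (CO2 leading the BOLD
#' response) and computes the Pearson correlation with the mean grey-matter
#' BOLD time course over the overlapping samples at each shift; the shift
#' maximizing r wins (smallest shift on ties). Shifts with fewer than 10
#' overlapping samples are skipped.
#'
#' @param gmMeanBold mean in-mask BOLD series (one value per volume).
#' @param endtidal an \linkS4class{EndTidalSeries} aligned to the same run.
#' @param step shift increment (s); use the run TR.
#' @param maxShift largest forward shift tested (s); default 18.
#' @return A \linkS4class{ShiftReport}.
#' @export
optimalShift <- function(gmMeanBold, endtidal, step, maxShift = 18) {
  stopifnot(is(endtidal, "EndTidalSeries"))
  pet <- endtidal@resampled
  if (length(gmMeanBold) != length(pet))
    stop("series lengths differ")
  if (step <= 0) stop("'step' must be positive")
  shifts <- seq(0, maxShift, by = step)
  n <- length(pet)
  r <- rep(NA_real_, length(shifts))
  for (i in seq_along(shifts)) {
    lag <- as.integer(round(shifts[i] / step))  # shift in whole volumes
    if (n - lag < 10L) {
      message(sprintf("optimalShift: shift %.1f s skipped (<10 overlapping samples)",
                      shifts[i]))
      next
    }
    a <- gmMeanBold[(lag + 1L):n]
    b <- pet[seq_len(n - lag)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r[i] <- stats::cor(a, b)
  }
  if (all(is.na(r))) stop("no shift had enough overlapping samples")
  best <- which.max(r)  # first maximum = smallest shift on ties
  new("ShiftReport", shiftsTested = shifts, correlations = r,
      chosenShift = shifts[best])
}

#' Shift an end-tidal series forward by whole volumes
#'
#' @param endtidal an \linkS4class{EndTidalSeries}.
#' @param shift forward shift (s), a multiple of the TR.
#' @param tr repetition time (s).
#' @return numeric regressor (one value per volume): the shifted resampled
#'   end-tidal series, front-filled with its first value.
#' @export
shiftedEndTidal <- function(endtidal, shift, tr) {
  k <- as.integer(round(shift / tr))
  pet <- endtidal@resampled
  if (k == 0) return(pet)
  c(rep(pet[1], k), pet)[seq_along(pet)]
}

#' Gas-challenge CVR map
#'
#' Fits a GLM with the optimally shifted end-tidal regressor (entered as
#' the baseline-subtracted series in mmHg, plus drift and optional motion
#' nuisance), extracts the CO2-contrast percent-signal-change map, and
#' divides it by the maximum end-tidal change to obtain CVR in %BOLD/mmHg.
#' The statistic map at the voxel criterion is returned alongside.
#'
#' @param run a gas-challenge \linkS4class{BoldRun}.
#' @param endtidal an \linkS4class{EndTidalSeries} for the run.
#' @param shift a \linkS4class{ShiftReport} (or a numeric shift in s).
#' @param motion optional motion matrix.
#' @param alpha voxel threshold recorded with the statistic map.
#' @return list with \code{cvr} (\linkS4class{CvrMap}), \code{psc},
#'   \code{stat}, \code{thresholdedCvr} (CVR restricted to voxels with
#'   p < alpha) and \code{fit}.
#' @export
fitGasCvr <- function(run, endtidal, shift, motion = NULL, alpha = 0.001) {
  stopifnot(is(run, "BoldRun"), is(endtidal, "EndTidalSeries"))
  if (endtidal@maxChange <= 0)
    stop("non-positive end-tidal change; cannot form CVR")
  sh <- if (is(shift, "ShiftReport")) shift@chosenShift else shift
  reg <- shiftedEndTidal(endtidal, sh, run@tr) - endtidal@baseline
  regr <- new("Regressor", name = "petco2", samples = reg,
              peakHeight = max(abs(reg)))
  des <- designMatrix(list(regr), nVolumes(run), run@tr, motion = motion)
  fit <- fitGlm(run, des)
  stat <- contrastT(fit, "petco2")
  psc <- percentSignalChange(fit, "petco2")
  cvrArr <- psc@psc / endtidal@maxChange
  cvr <- new("CvrMap", cvr = cvrArr, mask = psc@mask,
             units = "%BOLD/mmHg", maxChange = endtidal@maxChange)
  thr <- cvrArr
  thr[!(stat@p < alpha) | is.na(stat@p)] <- NA_real_
  thrMap <- new("CvrMap", cvr = thr, mask = psc@mask & !is.na(thr),
                units = "%BOLD/mmHg", maxChange = endtidal@maxChange)
  list(cvr = cvr, psc = psc, stat = stat, thresholdedCvr = thrMap,
       fit = fit)
}
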
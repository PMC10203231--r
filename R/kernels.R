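#' @include AllClasses.R
NULL

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional double-gamma HRF: a gamma density peaking near 5 s minus
#' a later, shallower undershoot gamma (response delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6), evaluated on a grid of
#' step \code{dt} over a 32 s support and peak-normalized to 1.
#'
#' @param dt sampling step in seconds (0 < dt <= 1).
#' @return A \linkS4class{ResponseKernel} of kind \code{"hrf"}.
#' @examples
#' h <- canonicalHrf(0.1)
#' kernelTimes(h)[which.max(kernelValues(h))]  # ~5 s
#' @export
canonicalHrf <- function(dt) {
  checkKernelDt(dt)
  support <- 32
  t <- seq(0, support, by = dt)
  v <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  new("ResponseKernel", dt = dt, values = v / max(v), kind = "hrf",
      support = support)
}

#' Respiratory response function
#'
#' The difference-of-gammas impulse response to a respiratory challenge:
#' an early positive peak near 3 s followed by a much deeper and longer
#' negative undershoot than the canonical HRF's, with non-negligible tail
#' mass out to about a minute (hence the 60 s default support):
#' \deqn{rrf(t) = 0.6\, t^{2.1} e^{-t/1.6} - 0.0023\, t^{3.54} e^{-t/4.25}}
#' Peak-normalized to 1. The coefficients follow the published formulation;
#' alternates can be supplied through \code{coef}.
#'
#' @param dt sampling step in seconds (0 < dt <= 1).
#' @param support kernel length in seconds (default 60).
#' @param coef named list of the four coefficients
#'   (\code{a1}, \code{tau1}, \code{a2}, \code{tau2}, \code{p1}, \code{p2}).
#' @return A \linkS4class{ResponseKernel} of kind \code{"rrf"}.
#' @export
respiratoryResponseFunction <- function(dt, support = 60,
    coef = list(a1 = 0.6, p1 = 2.1, tau1 = 1.6,
                a2 = 0.0023, p2 = 3.54, tau2 = 4.25)) {
  checkKernelDt(dt)
  t <- seq(0, support, by = dt)
  v <- coef$a1 * t^coef$p1 * exp(-t / coef$tau1) -
    coef$a2 * t^coef$p2 * exp(-t / coef$tau2)
  new("ResponseKernel", dt = dt, values = v / max(v), kind = "rrf",
      support = support)
}

checkKernelDt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt > 1)
    stop("'dt' must be a single value in (0, 1] seconds")
}

#' Write a kernel as a two-column TSV (time, amplitude)
#'
#' @param kernel a \linkS4class{ResponseKernel}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeKernelTsv <- function(kernel, path) {
  utils::write.table(
    data.frame(time = kernelTimes(kernel), amplitude = kernelValues(kernel)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Breath-hold ramp input series
#'
#' Models the accumulation of arterial CO2 over each breath-hold epoch: the
#' series rises linearly from 0 to 1 across every hold and is 0 during
#' paced breathing. By default the ramp resets at epoch end (the washout is
#' carried by the respiratory kernel's long undershoot); set
#' \code{extendIntoRest} to hold the plateau through the following rest
#' block instead.
#'
#' @param paradigm a breath-hold \linkS4class{ParadigmSpec}.
#' @param dt sampling step in seconds of the returned high-resolution series.
#' @param extendIntoRest logical; carry the end-of-hold plateau into the
#'   recovery period.
#' @return numeric vector sampled at \code{seq(0, totalDuration, by = dt)}
#'   (last point excluded).
#' @export
rampRegressor <- function(paradigm, dt, extendIntoRest = FALSE) {
  stopifnot(is(paradigm, "ParadigmSpec"))
  if (paradigm@kind != "breath_hold")
    stop("rampRegressor requires a breath_hold paradigm")
  on <- paradigm@onsets; du <- paradigm@durations
  if (any(on[-1] < (on + du)[-length(on)]))
    stop("breath-hold epochs overlap")
  t <- seq(0, paradigm@totalDuration - dt / 2, by = dt)
  x <- numeric(length(t))
  for (i in seq_along(on)) {
    inEpoch <- t >= on[i] & t < on[i] + du[i]
    x[inEpoch] <- (t[inEpoch] - on[i]) / du[i]
    if (extendIntoRest) {
      nxt <- if (i < length(on)) on[i + 1] else paradigm@totalDuration
      x[t >= on[i] + du[i] & t < nxt] <- 1
    }
  }
  x
}

#' Build a sampled model regressor by kernel convolution
#'
#' Convolves an event set (delta sticks at onset times) or an arbitrary
#' high-resolution input series with a response kernel at the kernel's
#' resolution, then samples the result at volume acquisition times
#' (volume onsets, \code{t = 0, tr, 2 tr, ...}). \code{onsetShift} delays
#' the input before convolution; it is how staggered-onset breath-hold
#' models are constructed. The regressor's \code{peakHeight} is the maximum
#' absolute amplitude of the high-resolution convolved series, the quantity
#' percent-signal-change scaling divides by.
#'
#' @param events either a numeric vector of onset times (s), in which case
#'   unit delta sticks are placed at those times, or a high-resolution
#'   series sampled at the kernel's \code{dt} starting at t = 0 (see
#'   \code{isSeries}).
#' @param kernel a \linkS4class{ResponseKernel}.
#' @param nVolumes number of volumes in the run.
#' @param tr repetition time (s).
#' @param onsetShift non-negative delay applied to the input (s).
#' @param isSeries interpret \code{events} as a series rather than onsets;
#'   by default series are detected by length (> 64 samples).
#' @param name column label for the resulting \linkS4class{Regressor}.
#' @return A \linkS4class{Regressor}.
#' @export
buildRegressor <- function(events, kernel, nVolumes, tr, onsetShift = 0,
                           isSeries = NULL, name = "task") {
  stopifnot(is(kernel, "ResponseKernel"))
  if (onsetShift < 0) stop("'onsetShift' must be >= 0")
  dt <- kernel@dt
  runDur <- nVolumes * tr
  nHi <- as.integer(round(runDur / dt))
  if (is.null(isSeries)) isSeries <- length(events) > 64L
  if (isSeries) {
    x <- numeric(nHi)
    m <- min(nHi, length(events))
    x[seq_len(m)] <- events[seq_len(m)]
    nShift <- as.integer(round(onsetShift / dt))
    if (nShift > 0) x <- c(numeric(nShift), x)[seq_len(nHi)]
  } else {
    on <- events + onsetShift
    drop <- on >= runDur
    if (any(drop)) {
      warning(sprintf("%d event(s) fall beyond the run end after shifting and were dropped",
                      sum(drop)))
      on <- on[!drop]
    }
    x <- numeric(nHi)
    idx <- pmin(nHi, as.integer(floor(on / dt)) + 1L)
    for (i in idx) x[i] <- x[i] + 1
  }
  k <- kernel@values
  conv <- convolveCausal(x, k)
  ph <- max(abs(conv))
  volIdx <- as.integer(round((seq_len(nVolumes) - 1L) * tr / dt)) + 1L
  new("Regressor", name = name, samples = conv[volIdx],
      peakHeight = if (ph > 0) ph else 1)
}

## causal FIR convolution truncated to the input length
convolveCausal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  out[seq_len(n)]
}
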
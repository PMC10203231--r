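#' @include AllClasses.R kernels.R phantom.R paradigms.R
NULL

#' Synthesize a capnograph trace for a gas-block paradigm
#'
#' Breath-by-breath CO2 partial pressure: a sinusoid at the breath period
#' (default 4 s) oscillating between the inspired floor (~0 mmHg) and an
#' end-tidal envelope that moves between the baseline plateau and the
#' hypercapnic plateau with exponential transitions at block edges
#' (time constant \code{transitionTau}; transitions essentially complete
#' within ~15 s at the default).
#'
#' @param paradigm a gas-block \linkS4class{ParadigmSpec}.
#' @param baselinePet,plateauPet end-tidal plateaus (mmHg); defaults emulate
#'   a 5\% CO2 challenge raising end-tidal CO2 from 35.38 to 45.19 mmHg.
#' @param breathPeriod breath cycle (s).
#' @param transitionTau exponential time constant of plateau transitions (s).
#' @param samplingDt trace sampling step (s, <= 0.1).
#' @return A \linkS4class{RespiratoryTrace}.
#' @export
synthesizeTrace <- function(paradigm, baselinePet = 35.38,
                            plateauPet = 45.19, breathPeriod = 4,
                            transitionTau = 5, samplingDt = 0.05) {
  stopifnot(is(paradigm, "ParadigmSpec"), paradigm@kind == "gas_block")
  t <- seq(0, paradigm@totalDuration, by = samplingDt)
  env <- petEnvelope(t, paradigm, baselinePet, plateauPet, transitionTau)
  co2 <- env * (0.5 - 0.5 * cos(2 * pi * t / breathPeriod))
  new("RespiratoryTrace", time = t, co2 = co2, breathPeriod = breathPeriod)
}

## end-tidal envelope with exponential block-edge transitions
petEnvelope <- function(t, paradigm, baselinePet, plateauPet, tau) {
  on <- paradigm@onsets[1]
  off <- on + paradigm@durations[1]
  env <- rep(baselinePet, length(t))
  rise <- t >= on & t < off
  env[rise] <- plateauPet + (baselinePet - plateauPet) *
    exp(-(t[rise] - on) / tau)
  post <- t >= off
  top <- plateauPet + (baselinePet - plateauPet) * exp(-(off - on) / tau)
  env[post] <- baselinePet + (top - baselinePet) * exp(-(t[post] - off) / tau)
  env
}

#' Simulate one BOLD run on a phantom
#'
#' Forward model per voxel:
#' \code{baseline * (1 + responseFraction(t)) + noise}, with Gaussian
#' temporal noise of sd \code{noiseSd/100 * baseline} (optionally AR(1)).
#' Breath-hold runs respond as a 0-to-1 ramp over each hold epoch convolved
#' with the respiratory response function, scaled so the run's peak percent
#' signal change equals \code{cvrSubject * deltaPetco2}. Gas runs respond as
#' the end-tidal envelope excursion times \code{cvrSubject/100}, dispersed
#' through a positive unit-area gamma kernel (width of the canonical HRF's
#' positive lobe) so plateau amplitudes are conserved. Event runs respond
#' as condition sticks convolved with the canonical HRF, scaled so the peak
#' PSC of the correct-trial regressor equals the subject's
#' \code{taskAmpTrue}; incorrect events carry an independent amplitude.
#' The per-subject hemodynamic delay is applied as a pure shift. Six
#' plausible motion-parameter columns are generated alongside (they are
#' nuisance bookkeeping; they do not corrupt the signal).
#'
#' @param phantom an \linkS4class{AtlasPhantom}.
#' @param truth a \linkS4class{GroundTruth} drawn for the phantom.
#' @param paradigm a \linkS4class{ParadigmSpec}.
#' @param subject subject index (1-based, <= cohort size).
#' @param noiseSd temporal noise (\% of baseline); default
#'   \code{truth@noiseSd}.
#' @param seed integer seed for the noise draw.
#' @param baseline baseline intensity of in-parcel voxels.
#' @param ar AR(1) coefficient for temporally correlated noise (0 = white).
#' @param incorrectAmp PSC amplitude of incorrect-trial responses (\%);
#'   default 0.5.
#' @param forceKernel for breath-hold runs, generate under \code{"rrf"}
#'   (default) or \code{"hrf"} — the latter creates the minority of
#'   subjects for whom the respiratory kernel is a poor fit.
#' @return A \linkS4class{BoldRun}; for gas runs \code{meta$trace} holds the
#'   matching \linkS4class{RespiratoryTrace}, and \code{meta$motion} the
#'   6-column motion table for every kind.
#' @export
simulateRun <- function(phantom, truth, paradigm, subject, noiseSd = NULL,
                        seed = 1, baseline = 1000, ar = 0,
                        incorrectAmp = 0.5, forceKernel = c("rrf", "hrf")) {
  stopifnot(is(phantom, "AtlasPhantom"), is(truth, "GroundTruth"),
            is(paradigm, "ParadigmSpec"))
  forceKernel <- match.arg(forceKernel)
  nSub <- ncol(truth@cvrSubject)
  if (subject < 1 || subject > nSub)
    stop(sprintf("subject index %d outside cohort of %d", subject, nSub))
  noiseSd <- noiseSd %||% truth@noiseSd
  tr <- paradigm@tr
  nVol <- nVolumes(paradigm)
  R <- nParcels(phantom)
  ## the per-subject delay models CO2 arrival/accumulation lag, a property
  ## of the vascular challenge; event-task responses use canonical latency
  lag <- if (paradigm@kind == "event_task") 0 else truth@subjectLag[subject]
  dt <- tr / 16

  trace <- NULL
  ## per-parcel response fraction over volumes (R x nVol)
  if (paradigm@kind == "breath_hold") {
    kern <- if (forceKernel == "rrf") respiratoryResponseFunction(dt)
            else canonicalHrf(dt)
    reg <- buildRegressor(rampRegressor(paradigm, dt), kern, nVol, tr,
                          onsetShift = lag, isSeries = TRUE)
    shape <- reg@samples / reg@peakHeight
    amp <- truth@cvrSubject[, subject] * truth@deltaPetco2 / 100
    frac <- outer(amp, shape)
  } else if (paradigm@kind == "gas_block") {
    tHi <- seq(0, nVol * tr - dt / 2, by = dt)
    env <- petEnvelope(tHi, paradigm, baselinePet = 35.38,
                       plateauPet = 35.38 + truth@deltaPetco2, tau = 5)
    delta <- env - env[1]
    k <- gasDispersionKernel(dt)
    hi <- convolveCausal(delta, k)
    nShift <- as.integer(round(lag / dt))
    if (nShift > 0) hi <- c(numeric(nShift), hi)[seq_along(hi)]
    shape <- hi[as.integer(round((seq_len(nVol) - 1L) * tr / dt)) + 1L]
    frac <- outer(truth@cvrSubject[, subject] / 100, shape)
    trace <- synthesizeTrace(paradigm, baselinePet = 35.38,
                             plateauPet = 35.38 + truth@deltaPetco2)
  } else {  # event_task
    hrf <- canonicalHrf(dt)
    correct <- if (length(paradigm@correctness)) paradigm@correctness
               else rep(TRUE, length(paradigm@onsets))
    regC <- buildRegressor(paradigm@onsets[correct], hrf, nVol, tr,
                           onsetShift = lag, isSeries = FALSE)
    shape <- regC@samples / regC@peakHeight
    amp <- truth@taskAmpTrue[, subject] / 100
    frac <- outer(amp, shape)
    if (any(!correct)) {
      regI <- buildRegressor(paradigm@onsets[!correct], hrf, nVol, tr,
                             onsetShift = lag, isSeries = FALSE)
      frac <- frac + rep(1, R) %o%
        (incorrectAmp / 100 * regI@samples / regI@peakHeight)
    }
  }

  lab <- phantom@labels
  mask <- lab > 0L
  nvox <- sum(mask)
  voxParcel <- as.integer(lab[mask])
  Y <- baseline * (1 + frac[voxParcel, , drop = FALSE])
  motion <- NULL
  withSeed(seed, {
    if (noiseSd > 0) {
      e <- matrix(stats::rnorm(nvox * nVol), nvox, nVol)
      if (ar > 0) {
        e <- t(apply(e, 1, function(z)
          stats::filter(z, ar, method = "recursive")))
        e <- e * sqrt(1 - ar^2)
      }
      Y <- Y + noiseSd / 100 * baseline * e
    }
    motion <- motionParams(nVol)
  })
  dat <- array(0, c(dim(lab), nVol))
  idx <- which(mask)
  for (v in seq_len(nVol))
    dat[idx + (v - 1L) * prod(dim(lab))] <- Y[, v]
  aff <- diag(c(phantom@voxelSize, 1))
  new("BoldRun", data = dat, tr = tr, mask = mask, affine = aff,
      meta = list(subject = subject, kind = paradigm@kind,
                  paradigm = paradigm, lag = lag, noiseSd = noiseSd,
                  seed = as.integer(seed), motion = motion,
                  generatorKernel = if (paradigm@kind == "breath_hold")
                    forceKernel else NA_character_,
                  trace = trace))
}

## positive-lobe gamma dispersion kernel, unit area: conserves plateau
## amplitudes of slow inputs (no undershoot-driven overshoot)
gasDispersionKernel <- function(dt, shape = 6, scale = 1, support = 32) {
  t <- seq(0, support, by = dt)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / sum(k)
}

## smooth random-walk motion parameters: 3 translations (mm), 3 rotations (rad)
motionParams <- function(nVol) {
  m <- apply(matrix(stats::rnorm(nVol * 6, 0, 0.02), nVol, 6), 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}
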
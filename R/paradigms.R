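#' @include AllClasses.R
NULL

#' Breath-hold block paradigm
#'
#' Default paced breath-holding challenge: 5 hold epochs of 13.5 s, each
#' preceded by 16.5 s of regular breathing, 2.5 min (150 s) in total.
#'
#' @param nEpochs number of hold epochs.
#' @param holdDuration hold length (s).
#' @param restDuration paced-breathing interval before each hold (s).
#' @param tr repetition time (s); the experiment-1 acquisition default is 2 s.
#' @return A \linkS4class{ParadigmSpec} of kind \code{"breath_hold"}.
#' @examples
#' p <- breathHoldParadigm()
#' p@totalDuration / 60  # 2.5 minutes
#' @export
breathHoldParadigm <- function(nEpochs = 5, holdDuration = 13.5,
                               restDuration = 16.5, tr = 2) {
  cycle <- holdDuration + restDuration
  onsets <- restDuration + cycle * (seq_len(nEpochs) - 1)
  new("ParadigmSpec", kind = "breath_hold", onsets = onsets,
      durations = rep(holdDuration, nEpochs),
      conditions = rep("breath_hold", nEpochs),
      correctness = logical(0),
      totalDuration = nEpochs * cycle, tr = tr)
}

#' Gas-challenge block paradigm
#'
#' Default hypercapnia protocol: 2 min of medical air, 2 min of a 5% CO2
#' mixture, 2 min of air (6 min total).
#'
#' @param airBefore,co2Duration,airAfter block lengths (s).
#' @param tr repetition time (s); the experiment-2 acquisition default is
#'   1.8 s.
#' @return A \linkS4class{ParadigmSpec} of kind \code{"gas_block"}.
#' @export
gasBlockParadigm <- function(airBefore = 120, co2Duration = 120,
                             airAfter = 120, tr = 1.8) {
  new("ParadigmSpec", kind = "gas_block", onsets = airBefore,
      durations = co2Duration, conditions = "co2",
      correctness = logical(0),
      totalDuration = airBefore + co2Duration + airAfter, tr = tr)
}

#' Generic event-related task paradigm
#'
#' Events with jittered inter-stimulus intervals, condition labels, and a
#' configurable fraction of incorrect responses (default 10%), so that
#' correct and incorrect trials can be modelled as separate regressors.
#'
#' @param nEvents number of trials.
#' @param conditions condition label pool sampled per trial.
#' @param eventDuration trial duration (s).
#' @param isiRange inter-stimulus interval range (s), drawn uniformly.
#' @param pIncorrect fraction of trials flagged incorrect.
#' @param tr repetition time (s).
#' @param seed integer seed.
#' @return A \linkS4class{ParadigmSpec} of kind \code{"event_task"}.
#' @export
eventTaskParadigm <- function(nEvents = 40, conditions = "task",
                              eventDuration = 1, isiRange = c(2, 6),
                              pIncorrect = 0.1, tr = 2, seed = 1) {
  withSeed(seed, {
    isi <- stats::runif(nEvents, isiRange[1], isiRange[2])
    onsets <- cumsum(isi + eventDuration) - eventDuration
    cond <- sample(rep_len(conditions, nEvents))
    nInc <- round(pIncorrect * nEvents)
    correct <- rep(TRUE, nEvents)
    if (nInc > 0) correct[sample.int(nEvents, nInc)] <- FALSE
    total <- ceiling((max(onsets) + eventDuration + 10) / tr) * tr
    new("ParadigmSpec", kind = "event_task", onsets = onsets,
        durations = rep(eventDuration, nEvents), conditions = cond,
        correctness = correct, totalDuration = total, tr = tr)
  })
}

#' Cued-flanker attention-network paradigm
#'
#' Emulates the onset/condition structure of a cued flanker attention task:
#' 72 trials per run of which 60 (83.3%) carry a visual cue (double, valid
#' or invalid spatial cue; 12 trials are uncued), target arrows congruent
#' or incongruent, pseudo-randomised inter-stimulus intervals of 2-12 s,
#' 260 volumes at TR 1.8 s (7 min 48 s per run).
#'
#' @param tr repetition time (s).
#' @param seed integer seed.
#' @param pIncorrect fraction of trials flagged incorrect.
#' @return A \linkS4class{ParadigmSpec} with conditions of the form
#'   \code{"<cue>_<congruency>"} (cue in nocue/double/valid/invalid).
#' @examples
#' p <- antrParadigm()
#' nVolumes(p)                                   # 260
#' mean(grepl("nocue", p@conditions) == FALSE)   # 0.833
#' @export
antrParadigm <- function(tr = 1.8, seed = 1, pIncorrect = 0.1) {
  nTrials <- 72L
  nVol <- 260L
  total <- nVol * tr  # 468 s = 7 min 48 s
  cues <- c(rep("nocue", 12), rep("double", 24), rep("valid", 24),
            rep("invalid", 12))
  withSeed(seed, {
    cues <- sample(cues)
    cong <- sample(rep(c("congruent", "incongruent"), length.out = nTrials))
    ## trial = 0.5 s target; ISI pseudo-randomised 2-12 s, scaled to fit
    isi <- stats::runif(nTrials, 2, 12)
    isi <- isi * (total - 10 - nTrials * 0.5) / sum(isi)
    onsets <- cumsum(isi + 0.5) - 0.5
    nInc <- round(pIncorrect * nTrials)
    correct <- rep(TRUE, nTrials)
    if (nInc > 0) correct[sample.int(nTrials, nInc)] <- FALSE
    new("ParadigmSpec", kind = "event_task", onsets = onsets,
        durations = rep(0.5, nTrials),
        conditions = paste(cues, cong, sep = "_"),
        correctness = correct, totalDuration = total, tr = tr)
  })
}

#' Stop-signal paradigm
#'
#' Emulates the onset/condition structure of a stop-signal response
#' inhibition task: 128 one-second trials of which 32 (25%) are stop
#' trials, separated by a jittered fixation baseline.
#'
#' @param tr repetition time (s).
#' @param seed integer seed.
#' @param pIncorrect fraction of trials flagged incorrect (failed stops /
#'   failed gos).
#' @return A \linkS4class{ParadigmSpec} with conditions \code{"go"} /
#'   \code{"stop"}.
#' @export
stopSignalParadigm <- function(tr = 2, seed = 1, pIncorrect = 0.1) {
  nTrials <- 128L
  cond <- c(rep("go", 96), rep("stop", 32))
  withSeed(seed, {
    cond <- sample(cond)
    isi <- stats::runif(nTrials, 1, 3)
    onsets <- cumsum(isi + 1) - 1
    nInc <- round(pIncorrect * nTrials)
    correct <- rep(TRUE, nTrials)
    if (nInc > 0) correct[sample.int(nTrials, nInc)] <- FALSE
    total <- ceiling((max(onsets) + 1 + 12) / tr) * tr
    new("ParadigmSpec", kind = "event_task", onsets = onsets,
        durations = rep(1, nTrials), conditions = cond,
        correctness = correct, totalDuration = total, tr = tr)
  })
}

#' Summarize a paradigm's bookkeeping quantities
#'
#' Reports the quantities design descriptions are usually checked against:
#' total duration (s and min), volume count at the paradigm TR, event count,
#' per-condition counts and percentages, and the percentage of cued trials
#' for cued designs (conditions not labelled \code{nocue}).
#'
#' @param paradigm a \linkS4class{ParadigmSpec}.
#' @return A list with elements \code{duration_s}, \code{duration_min},
#'   \code{n_volumes}, \code{n_events}, \code{condition_counts},
#'   \code{condition_pct}, and \code{cued_pct} (NA when not applicable).
#' @export
paradigmSummary <- function(paradigm) {
  stopifnot(is(paradigm, "ParadigmSpec"))
  counts <- table(paradigm@conditions)
  nEv <- length(paradigm@onsets)
  cued <- if (paradigm@kind == "event_task" &&
              any(grepl("^nocue", paradigm@conditions)))
    fmtPct(sum(!grepl("^nocue", paradigm@conditions)), nEv) else NA_real_
  list(duration_s = paradigm@totalDuration,
       duration_min = paradigm@totalDuration / 60,
       n_volumes = nVolumes(paradigm),
       n_events = nEv,
       condition_counts = as.list(counts),
       condition_pct = lapply(as.list(counts), function(k) fmtPct(k, nEv)),
       cued_pct = cued)
}
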
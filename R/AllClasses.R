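#' @import methods
NULL

#' Atlas-labelled phantom parcellation
#'
#' A rectangular voxel grid carved into connected, integer-labelled parcels
#' emulating a cortical atlas (default 68 regions, mirroring a
#' Desikan-Killiany-style parcellation). Label 0 is background; parcels are
#' labelled 1..R contiguously. Phantoms built by \code{generatePhantom}
#' guarantee at least 20 voxels per parcel; hand-built toy atlases may be
#' smaller.
#'
#' @slot labels integer 3D array of parcel labels (0 = background).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot labelTable data.frame with columns \code{label}, \code{region},
#'   \code{hemisphere}, \code{n_voxels}.
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("AtlasPhantom",
  representation(labels = "array", voxelSize = "numeric",
                 labelTable = "data.frame", seed = "integer"),
  validity = function(object) {
    lab <- object@labels
    if (length(dim(lab)) != 3L) return("labels must be a 3D array")
    u <- sort(unique(as.integer(lab[lab > 0])))
    if (length(u) && !identical(u, seq_len(max(u))))
      return("parcel labels must be contiguous integers starting at 1")
    cnt <- tabulate(as.integer(lab[lab > 0]))
    if (length(cnt) && any(cnt < 1L))
      return("every parcel must contain at least one voxel")
    if (nrow(object@labelTable) != length(u))
      return("labelTable rows must match the number of parcels")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive lengths (mm)")
    TRUE
  })

#' Ground truth for a simulated cohort
#'
#' The generative parameters a phantom study is built from: per-parcel
#' population CVR (lognormal across parcels), per-subject CVR (a lognormal
#' subject factor on the parcel value, since between-subject reactivity
#' differences are what the per-region coupling regressions measure), and
#' task amplitudes obeying the linear coupling model
#' \code{task = intercept + slope * (cvr_subject * deltaPetco2) + noise}.
#'
#' @slot cvrTrue numeric per-parcel population CVR (%BOLD/mmHg).
#' @slot cvrSubject matrix (parcel x subject) of subject-level CVR.
#' @slot taskAmpTrue matrix (parcel x subject) of task PSC (%).
#' @slot couplingSlope,couplingIntercept scalars of the linear coupling model.
#' @slot subjectLag numeric per-subject hemodynamic delay (s).
#' @slot subjectSd residual task-amplitude noise sd (%).
#' @slot deltaPetco2 nominal hypercapnic end-tidal rise (mmHg).
#' @slot noiseSd default temporal noise scale (% of baseline).
#' @slot seed integer seed.
#' @export
setClass("GroundTruth",
  representation(cvrTrue = "numeric", cvrSubject = "matrix",
                 taskAmpTrue = "matrix", couplingSlope = "numeric",
                 couplingIntercept = "numeric", subjectLag = "numeric",
                 subjectSd = "numeric", deltaPetco2 = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@cvrTrue <= 0)) return("cvrTrue must be positive")
    if (!identical(dim(object@cvrSubject), dim(object@taskAmpTrue)))
      return("cvrSubject and taskAmpTrue must have matching dimensions")
    if (nrow(object@cvrSubject) != length(object@cvrTrue))
      return("cvrSubject rows must match the number of parcels")
    if (length(object@subjectLag) != ncol(object@cvrSubject))
      return("subjectLag must have one entry per subject")
    if (object@deltaPetco2 <= 0) return("deltaPetco2 must be positive")
    TRUE
  })

#' Stimulus paradigm specification
#'
#' Event/block timing for a run: breath-hold blocks (default 5 holds of
#' 13.5 s separated by 16.5 s of paced breathing, 2.5 min total), a gas
#' block design (default 2 min air / 2 min 5\% CO2 / 2 min air), or an
#' event-related cognitive design with per-event condition labels and
#' response correctness.
#'
#' @slot kind one of \code{"breath_hold"}, \code{"gas_block"},
#'   \code{"event_task"}.
#' @slot onsets,durations numeric, seconds from run start.
#' @slot conditions character label per event.
#' @slot correctness logical per event (event tasks only).
#' @slot totalDuration run length (s).
#' @slot tr repetition time (s).
#' @export
setClass("ParadigmSpec",
  representation(kind = "character", onsets = "numeric",
                 durations = "numeric", conditions = "character",
                 correctness = "logical", totalDuration = "numeric",
                 tr = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("breath_hold", "gas_block", "event_task"))
      return("unknown paradigm kind")
    if (is.unsorted(object@onsets, strictly = TRUE))
      return("onsets must be strictly increasing")
    if (length(object@onsets) != length(object@durations))
      return("onsets and durations must have equal length")
    if (any(object@onsets + object@durations > object@totalDuration + 1e-9))
      return("events must end within totalDuration")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })

#' Synthetic capnograph trace
#'
#' A uniformly sampled CO2 partial-pressure trace oscillating at the breath
#' period between an inspired floor and an end-tidal envelope which rises
#' from the baseline plateau to the hypercapnic plateau during the CO2
#' block.
#'
#' @slot time numeric, seconds (uniform sampling, step <= 0.1 s).
#' @slot co2 numeric, partial pressure (mmHg).
#' @slot breathPeriod breath cycle length (s).
#' @export
setClass("RespiratoryTrace",
  representation(time = "numeric", co2 = "numeric", breathPeriod = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@co2))
      return("time and co2 must have equal length")
    dt <- diff(object@time)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6)
      return("time must be uniformly increasing")
    if (length(dt) && dt[1] > 0.1 + 1e-9)
      return("sampling interval must be <= 0.1 s")
    if (object@breathPeriod <= 0) return("breathPeriod must be positive")
    TRUE
  })

#' One 4D BOLD acquisition
#'
#' @slot data numeric 4D array (x, y, z, volume).
#' @slot tr repetition time (s).
#' @slot mask logical 3D array of analyzed voxels.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot meta list of run metadata (subject, task, paradigm, ...).
#' @export
setClass("BoldRun",
  representation(data = "array", tr = "numeric", mask = "array",
                 affine = "matrix", meta = "list"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L) return("data must be 4D")
    if (!identical(dim(object@mask), dim(object@data)[1:3]))
      return("mask shape must match the spatial grid")
    if (object@tr <= 0) return("tr must be positive")
    if (!identical(dim(object@affine), c(4L, 4L)))
      return("affine must be 4x4")
    TRUE
  })

#' Hemodynamic or respiratory impulse-response kernel
#'
#' @slot dt sampling step (s).
#' @slot values amplitude samples, peak-normalized to max = 1.
#' @slot kind \code{"hrf"} or \code{"rrf"}.
#' @slot support kernel length (s).
#' @export
setClass("ResponseKernel",
  representation(dt = "numeric", values = "numeric", kind = "character",
                 support = "numeric"),
  validity = function(object) {
    if (object@dt <= 0) return("dt must be positive")
    if (!object@kind %in% c("hrf", "rrf")) return("kind must be hrf or rrf")
    if (abs(max(object@values) - 1) > 1e-9)
      return("kernel must be peak-normalized to 1")
    if (object@kind == "hrf" && sum(object@values) * object@dt <= 0)
      return("hrf must integrate to a positive value")
    TRUE
  })

#' A model regressor sampled at volume times
#'
#' @slot name column label.
#' @slot samples amplitude per volume.
#' @slot peakHeight maximum absolute amplitude of the underlying
#'   high-resolution convolved series, used to scale contrast estimates to
#'   percent signal change.
#' @export
setClass("Regressor",
  representation(name = "character", samples = "numeric",
                 peakHeight = "numeric"),
  validity = function(object) {
    if (length(object@peakHeight) != 1L || is.na(object@peakHeight))
      return("peakHeight must be a single number")
    TRUE
  })

#' Column-labelled design matrix aligned to a run
#'
#' @slot values volumes x columns numeric matrix.
#' @slot tr repetition time (s).
#' @slot peakHeights named numeric, high-resolution peak height per task
#'   regressor column (NA for nuisance columns).
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", tr = "numeric", peakHeights = "numeric"),
  validity = function(object) {
    X <- object@values
    cn <- colnames(X)
    if (is.null(cn) || anyDuplicated(cn)) return("column names must be unique")
    if (sum(cn == "constant") != 1L)
      return("exactly one 'constant' column is required")
    if (qr(X)$rank < ncol(X)) {
      dep <- dependentColumns(X)
      return(paste0("design matrix is rank deficient; dependent columns: ",
                    paste(dep, collapse = ", ")))
    }
    TRUE
  })

dependentColumns <- function(X) {
  q <- qr(X)
  bad <- setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])
  colnames(X)[bad]
}

#' Per-voxel GLM fit
#'
#' @slot betas matrix (in-mask voxels x design columns).
#' @slot sigma2 per-voxel residual variance.
#' @slot dof residual degrees of freedom (volumes - rank of design).
#' @slot design the \linkS4class{DesignMatrix} used.
#' @slot mask logical 3D array of fitted voxels.
#' @slot dims spatial grid dimensions.
#' @export
setClass("GlmResult",
  representation(betas = "matrix", sigma2 = "numeric", dof = "numeric",
                 design = "DesignMatrix", mask = "array", dims = "integer"),
  validity = function(object) {
    if (any(object@sigma2 < 0)) return("sigma2 must be non-negative")
    if (nrow(object@betas) != sum(object@mask))
      return("betas rows must match in-mask voxel count")
    TRUE
  })

#' Voxel-wise t statistic map
#'
#' @slot t,p 3D arrays (NA outside the analyzed mask); p is the one-sided
#'   upper-tail probability unless computed otherwise.
#' @slot contrast contrast weight vector.
#' @slot dof degrees of freedom.
#' @slot mask logical 3D array.
#' @export
setClass("StatMap",
  representation(t = "array", p = "array", contrast = "numeric",
                 dof = "numeric", mask = "array"))

#' Voxel-wise percent-signal-change map
#'
#' @slot psc 3D array (%); NA outside the mask (and outside the retained set
#'   after thresholding).
#' @slot contrast contrast weights.
#' @slot baseline per-voxel baseline estimate (constant-column beta).
#' @slot mask logical 3D array of defined voxels.
#' @export
setClass("PscMap",
  representation(psc = "array", contrast = "numeric", baseline = "array",
                 mask = "array"))

#' Cerebrovascular reactivity map
#'
#' @slot cvr 3D array, %BOLD per mmHg (gas challenge) or breath-hold PSC
#'   surrogate (%).
#' @slot mask logical 3D array.
#' @slot units character, e.g. \code{"%BOLD/mmHg"}.
#' @slot maxChange end-tidal change used as the divisor (mmHg; NA for the
#'   breath-hold surrogate).
#' @export
setClass("CvrMap",
  representation(cvr = "array", mask = "array", units = "character",
                 maxChange = "numeric"))

#' End-tidal CO2 series extracted from a capnograph trace
#'
#' @slot breathTimes times of detected end-tidal peaks (s).
#' @slot petco2 end-tidal partial pressure per breath (mmHg).
#' @slot resampled end-tidal series linearly interpolated at volume times.
#' @slot volTimes volume acquisition times (s).
#' @slot baseline mean end-tidal value over the pre-challenge window (mmHg).
#' @slot maxChange max(resampled) - baseline (mmHg).
#' @export
setClass("EndTidalSeries",
  representation(breathTimes = "numeric", petco2 = "numeric",
                 resampled = "numeric", volTimes = "numeric",
                 baseline = "numeric", maxChange = "numeric"),
  validity = function(object) {
    if (length(object@breathTimes) != length(object@petco2))
      return("breathTimes and petco2 must have equal length")
    if (length(object@resampled) != length(object@volTimes))
      return("resampled must align with volTimes")
    TRUE
  })

#' Staggered-onset lag search report
#'
#' @slot lagsTested lags evaluated (s).
#' @slot sigVoxelCounts significant-voxel count per lag at the selection
#'   threshold.
#' @slot chosenLag winning lag (s); ties resolved toward the smallest lag.
#' @slot chosenKernel \code{"rrf"} or \code{"hrf"}.
#' @slot fallbackUsed TRUE when the respiratory kernel was abandoned for the
#'   canonical HRF.
#' @slot warning TRUE when no lag produced any significant voxels.
#' @export
setClass("LagSearchReport",
  representation(lagsTested = "numeric", sigVoxelCounts = "integer",
                 chosenLag = "numeric", chosenKernel = "character",
                 fallbackUsed = "logical", warning = "logical"),
  validity = function(object) {
    if (!object@chosenLag %in% object@lagsTested)
      return("chosenLag must be one of lagsTested")
    if (length(object@sigVoxelCounts) != length(object@lagsTested))
      return("one significant-voxel count per tested lag is required")
    TRUE
  })

#' End-tidal/BOLD cross-correlation shift report
#'
#' @slot shiftsTested shifts evaluated (s).
#' @slot correlations Pearson r per shift (NA where skipped).
#' @slot chosenShift shift maximizing r (smallest on ties).
#' @export
setClass("ShiftReport",
  representation(shiftsTested = "numeric", correlations = "numeric",
                 chosenShift = "numeric"),
  validity = function(object) {
    ok <- is.finite(object@correlations)
    if (any(abs(object@correlations[ok]) > 1 + 1e-12))
      return("correlations must lie in [-1, 1]")
    if (!object@chosenShift %in% object@shiftsTested)
      return("chosenShift must be one of shiftsTested")
    TRUE
  })
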
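#' @include AllClasses.R
NULL

#' Accessors for cvrcoupling objects
#'
#' Small accessor family: \code{nParcels} and \code{parcelLabels} for
#' phantoms, \code{cvrTrue}/\code{taskAmpTrue} for ground truth,
#' \code{boldData}/\code{brainMask}/\code{repetitionTime} for runs,
#' \code{designValues} for design matrices and \code{nVolumes} for
#' paradigms and runs.
#'
#' @param x an object of the documented class.
#' @return The slot contents; see individual methods.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setGeneric("cvrTrue", function(x) standardGeneric("cvrTrue"))

#' @rdname accessors
#' @export
setGeneric("taskAmpTrue", function(x) standardGeneric("taskAmpTrue"))

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("designValues", function(x) standardGeneric("designValues"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname accessors
#' @export
setGeneric("kernelTimes", function(x) standardGeneric("kernelTimes"))

setMethod("nParcels", "AtlasPhantom", function(x) nrow(x@labelTable))
setMethod("parcelLabels", "AtlasPhantom", function(x) x@labelTable$label)
setMethod("cvrTrue", "GroundTruth", function(x) x@cvrTrue)
setMethod("taskAmpTrue", "GroundTruth", function(x) x@taskAmpTrue)
setMethod("boldData", "BoldRun", function(x) x@data)
setMethod("brainMask", "BoldRun", function(x) x@mask)
setMethod("repetitionTime", "BoldRun", function(x) x@tr)
setMethod("repetitionTime", "ParadigmSpec", function(x) x@tr)
setMethod("designValues", "DesignMatrix", function(x) x@values)
setMethod("nVolumes", "BoldRun", function(x) dim(x@data)[4])
setMethod("nVolumes", "ParadigmSpec",
          function(x) as.integer(round(x@totalDuration / x@tr)))
setMethod("kernelValues", "ResponseKernel", function(x) x@values)
setMethod("kernelTimes", "ResponseKernel",
          function(x) seq(0, by = x@dt, length.out = length(x@values)))

setMethod("show", "AtlasPhantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("AtlasPhantom: %d parcels on a %dx%dx%d grid (%.1f mm voxels)\n",
              nParcels(object), d[1], d[2], d[3], object@voxelSize[1]))
  cat(sprintf("  parcel sizes: %d-%d voxels\n",
              min(object@labelTable$n_voxels), max(object@labelTable$n_voxels)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d parcels x %d subjects\n",
              nrow(object@cvrSubject), ncol(object@cvrSubject)))
  cat(sprintf("  coupling: task = %.3g + %.3g * bhPSC (+ noise sd %.3g)\n",
              object@couplingIntercept, object@couplingSlope, object@subjectSd))
  cat(sprintf("  CVR median %.3g %%/mmHg; deltaPetCO2 %.3g mmHg\n",
              stats::median(object@cvrTrue), object@deltaPetco2))
})

setMethod("show", "ParadigmSpec", function(object) {
  cat(sprintf("ParadigmSpec <%s>: %d events, %.1f s total, TR %.2f s\n",
              object@kind, length(object@onsets), object@totalDuration,
              object@tr))
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldRun: %dx%dx%d grid, %d volumes, TR %.2f s, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], object@tr, sum(object@mask)))
})

setMethod("show", "ResponseKernel", function(object) {
  tt <- kernelTimes(object)
  cat(sprintf("ResponseKernel <%s>: dt %.3g s, support %.0f s, peak at %.2f s\n",
              object@kind, object@dt, object@support, tt[which.max(object@values)]))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d columns (TR %.2f s)\n",
              nrow(object@values), ncol(object@values), object@tr))
  cat("  columns:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("GlmResult: %d voxels, %d columns, dof %d\n",
              nrow(object@betas), ncol(object@betas), object@dof))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: dof %d, t range [%.2f, %.2f] over %d voxels\n",
              object@dof, min(object@t, na.rm = TRUE),
              max(object@t, na.rm = TRUE), sum(object@mask)))
})

setMethod("show", "PscMap", function(object) {
  n <- sum(is.finite(object@psc))
  cat(sprintf("PscMap: %d defined voxels, PSC range [%.2f, %.2f]%%\n", n,
              suppressWarnings(min(object@psc, na.rm = TRUE)),
              suppressWarnings(max(object@psc, na.rm = TRUE))))
})

setMethod("show", "CvrMap", function(object) {
  cat(sprintf("CvrMap (%s): %d defined voxels, median %.3g\n", object@units,
              sum(is.finite(object@cvr)),
              stats::median(object@cvr, na.rm = TRUE)))
})

setMethod("show", "LagSearchReport", function(object) {
  cat(sprintf("LagSearchReport: chose lag %.1f s with kernel %s%s\n",
              object@chosenLag, object@chosenKernel,
              if (object@fallbackUsed) " (HRF fallback)" else ""))
  cat("  counts:", paste(sprintf("%g s=%d", object@lagsTested,
                                 object@sigVoxelCounts), collapse = ", "), "\n")
})

setMethod("show", "ShiftReport", function(object) {
  cat(sprintf("ShiftReport: chose shift %.1f s (r = %.3f)\n",
              object@chosenShift,
              object@correlations[match(object@chosenShift,
                                        object@shiftsTested)]))
})

setMethod("show", "EndTidalSeries", function(object) {
  cat(sprintf("EndTidalSeries: %d breaths, baseline %.2f mmHg, max change %.2f mmHg\n",
              length(object@petco2), object@baseline, object@maxChange))
})
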
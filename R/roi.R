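#' @include AllClasses.R utils.R
NULL

#' Extract per-region samples from thresholded maps
#'
#' For every atlas parcel, averages the task PSC and the CVR value over
#' the voxels where both thresholded maps are defined (the joint
#' significant-task and significant-vascular-response selection). Parcels
#' whose intersection is empty are omitted.
#'
#' @param taskPsc a thresholded \linkS4class{PscMap} (NA outside the
#'   retained voxels).
#' @param cvrMap a thresholded \linkS4class{PscMap} or
#'   \linkS4class{CvrMap}.
#' @param atlas an \linkS4class{AtlasPhantom} on the same grid.
#' @param subject subject identifier recorded on each row.
#' @return data.frame with columns \code{subject}, \code{roi},
#'   \code{task_psc}, \code{cvr_value}, \code{n_voxels}.
#' @export
extractRoiSamples <- function(taskPsc, cvrMap, atlas, subject) {
  stopifnot(is(atlas, "AtlasPhantom"))
  taskArr <- taskPsc@psc
  cvrArr <- if (is(cvrMap, "CvrMap")) cvrMap@cvr else cvrMap@psc
  if (!identical(dim(taskArr), dim(atlas@labels)) ||
      !identical(dim(cvrArr), dim(atlas@labels)))
    stop("atlas and map grids do not match")
  both <- !is.na(taskArr) & !is.na(cvrArr) & atlas@labels > 0L
  if (!any(both))
    return(data.frame(subject = character(0), roi = integer(0),
                      task_psc = numeric(0), cvr_value = numeric(0),
                      n_voxels = integer(0)))
  lab <- atlas@labels[both]
  tv <- tapply(taskArr[both], lab, mean)
  cv <- tapply(cvrArr[both], lab, mean)
  nv <- tapply(rep(1L, sum(both)), lab, sum)
  data.frame(subject = as.character(subject),
             roi = as.integer(names(tv)),
             task_psc = as.numeric(tv), cvr_value = as.numeric(cv),
             n_voxels = as.integer(nv), row.names = NULL)
}

#' Mean-absolute-deviation outlier filter
#'
#' Removes values whose absolute deviation from the center exceeds
#' \code{k} times the mean absolute deviation (single pass, no
#' re-iteration). This is the vascular-outlier rule applied to per-region
#' CVR values (large draining vessels inflate regional reactivity).
#' The center and deviation are mean-based by default; a median-centred
#' variant is available.
#'
#' @param values numeric vector (>= 3 values).
#' @param k deviation multiplier (default 3).
#' @param center \code{"mean"} (literal mean absolute deviation) or
#'   \code{"median"}.
#' @return list with \code{retained} (values), \code{keep} (logical index)
#'   and \code{excluded} (integer positions removed); all-identical input
#'   removes nothing.
#' @export
madFilter <- function(values, k = 3, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values) < 3) stop("madFilter needs at least 3 values")
  c0 <- if (center == "mean") mean(values) else stats::median(values)
  dev <- abs(values - c0)
  madv <- mean(dev)
  keep <- dev <= k * madv
  list(retained = values[keep], keep = keep, excluded = which(!keep),
       center = center)
}

#' Standard-deviation pair filter
#'
#' Removes sample pairs where either coordinate lies more than \code{k}
#' standard deviations from its group mean (single pass, both coordinates
#' by default). A zero-variance coordinate removes nothing on that
#' coordinate.
#'
#' @param pairs data.frame or matrix with two numeric columns.
#' @param k multiplier (default 3).
#' @param coords \code{"both"} or \code{"first"} (filter only the first
#'   column).
#' @return list with \code{retained} (the surviving rows), \code{keep}
#'   and \code{excluded}.
#' @export
sdFilter <- function(pairs, k = 3, coords = c("both", "first")) {
  coords <- match.arg(coords)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3) stop("sdFilter needs at least 3 pairs")
  zOut <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(FALSE, length(x))
    else abs(x - mean(x)) > k * s
  }
  out <- zOut(pairs[[1]])
  if (coords == "both") out <- out | zOut(pairs[[2]])
  keep <- !out
  list(retained = pairs[keep, , drop = FALSE], keep = keep,
       excluded = which(out))
}

#' Per-region coupling regressions with FDR control
#'
#' Pools samples across subjects and, for each region surviving the
#' outlier filters with at least \code{minN} subjects, fits ordinary least
#' squares of task PSC on the vascular value (breath-hold PSC or CVR).
#' Two-sided slope p-values are corrected across the region family by the
#' Benjamini-Hochberg step-up procedure at level \code{q}. Filter order:
#' the MAD rule on the vascular values first, then the pairwise SD rule
#' immediately before each regression.
#'
#' @param samples data.frame as returned by \code{\link{extractRoiSamples}}
#'   (rows pooled over subjects).
#' @param minN minimum subjects per region (default 10, >= 3).
#' @param q FDR level (default 0.05).
#' @param madK,sdK filter multipliers.
#' @param madCenter \code{"mean"} or \code{"median"} centring for the MAD
#'   rule.
#' @return data.frame with one row per evaluated region: \code{roi},
#'   \code{slope}, \code{intercept}, \code{r2}, \code{p}, \code{p_fdr},
#'   \code{n}, \code{excluded_outliers}, \code{fdr_significant},
#'   \code{slope_lo}, \code{slope_hi} (95\% slope interval). The filter
#'   convention used is recorded in \code{attr(, "mad_center")}.
#' @export
roiRegressions <- function(samples, minN = 10, q = 0.05, madK = 3,
                           sdK = 3, madCenter = c("mean", "median")) {
  madCenter <- match.arg(madCenter)
  if (minN < 3) stop("'minN' must be >= 3")
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  rois <- sort(unique(samples$roi))
  rows <- lapply(rois, function(rr) {
    s <- samples[samples$roi == rr, , drop = FALSE]
    nExcl <- 0L
    if (nrow(s) >= 3) {
      mf <- madFilter(s$cvr_value, k = madK, center = madCenter)
      nExcl <- nExcl + length(mf$excluded)
      s <- s[mf$keep, , drop = FALSE]
    }
    if (nrow(s) >= 3) {
      sf <- sdFilter(s[, c("task_psc", "cvr_value")], k = sdK)
      nExcl <- nExcl + length(sf$excluded)
      s <- s[sf$keep, , drop = FALSE]
    }
    if (nrow(s) < minN) return(NULL)
    fit <- stats::lm(task_psc ~ cvr_value, data = s)
    sm <- summary(fit)
    co <- stats::coef(sm)
    ci <- stats::confint(fit, "cvr_value", level = 0.95)
    p <- if (nrow(co) >= 2 && is.finite(co[2, 4])) co[2, 4] else 1
    data.frame(roi = rr, slope = co[2, 1], intercept = co[1, 1],
               r2 = sm$r.squared, p = min(max(p, .Machine$double.xmin), 1),
               n = nrow(s), excluded_outliers = nExcl,
               slope_lo = ci[1], slope_hi = ci[2], row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(roi = integer(0), slope = numeric(0),
                      intercept = numeric(0), r2 = numeric(0),
                      p = numeric(0), n = integer(0),
                      excluded_outliers = integer(0),
                      slope_lo = numeric(0), slope_hi = numeric(0),
                      p_fdr = numeric(0), fdr_significant = logical(0))
    attr(out, "mad_center") <- madCenter
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$fdr_significant <- out$p_fdr < q
  attr(out, "mad_center") <- madCenter
  out
}

#' Summarize region regression results
#'
#' @param results data.frame from \code{\link{roiRegressions}}.
#' @param topK how many top regions (by p) to tabulate.
#' @param labelTable optional atlas label table for region names.
#' @return list with \code{n_evaluated}, \code{n_significant},
#'   \code{pct_significant} (one decimal), \code{pooled_slope}
#'   (inverse-variance weighted mean of per-region slopes), \code{top}
#'   (top-K table ordered by p) and \code{r2_export} (region, r2,
#'   significant — polar-plot-ready).
#' @export
summarizeRoi <- function(results, topK = 10, labelTable = NULL) {
  if (!nrow(results)) stop("no regression results to summarize")
  nEval <- nrow(results)
  nSig <- sum(results$fdr_significant)
  se <- (results$slope_hi - results$slope_lo) / (2 * stats::qt(
    0.975, pmax(results$n - 2, 1)))
  wOk <- is.finite(se) & se > 0
  pooled <- if (any(wOk))
    sum(results$slope[wOk] / se[wOk]^2) / sum(1 / se[wOk]^2)
  else mean(results$slope)
  ord <- order(results$p)
  top <- results[ord[seq_len(min(topK, nEval))],
                 c("roi", "p", "r2", "n", "slope")]
  r2exp <- results[, c("roi", "r2", "fdr_significant")]
  if (!is.null(labelTable)) {
    m <- match(r2exp$roi, labelTable$label)
    r2exp$region <- labelTable$region[m]
    r2exp$hemisphere <- labelTable$hemisphere[m]
  }
  list(n_evaluated = nEval, n_significant = nSig,
       pct_significant = fmtPct(nSig, nEval), pooled_slope = pooled,
       top = top, r2_export = r2exp)
}
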
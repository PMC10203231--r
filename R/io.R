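#' @include AllClasses.R
NULL

#' Write a BOLD run as NIfTI plus JSON sidecar
#'
#' @param run a \linkS4class{BoldRun}.
#' @param path output file stem or \code{.nii} path; a \code{.json}
#'   sidecar recording the repetition time is written alongside, plus a
#'   motion TSV when the run carries motion parameters.
#' @return character vector of files written, invisibly.
#' @export
writeBoldRun <- function(run, path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  nii <- paste0(stem, ".nii")
  img <- RNifti::asNifti(run@data)
  RNifti::pixdim(img) <- c(abs(diag(run@affine)[1:3]), run@tr)
  RNifti::writeNifti(img, nii)
  side <- paste0(stem, ".json")
  jsonlite::write_json(list(RepetitionTime = run@tr,
                            Subject = run@meta$subject %||% NA,
                            Kind = run@meta$kind %||% NA),
                       side, auto_unbox = TRUE, digits = NA)
  files <- c(nii, side)
  if (!is.null(run@meta$motion)) {
    mo <- paste0(stem, "_motion.tsv")
    utils::write.table(run@meta$motion, mo, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    files <- c(files, mo)
  }
  invisible(files)
}

#' Read a BOLD run written by \code{writeBoldRun}
#'
#' Validates the sidecar repetition time against \code{expectTr} when
#' given; a mismatch is an error.
#'
#' @param path the \code{.nii} file (sidecar found by name).
#' @param mask optional logical 3D mask; default: voxels with nonzero
#'   temporal mean.
#' @param expectTr optional TR (s) the sidecar must match.
#' @return A \linkS4class{BoldRun}.
#' @export
readBoldRun <- function(path, mask = NULL, expectTr = NULL) {
  if (!file.exists(path)) stop("missing BOLD file: ", path)
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim(img))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  side <- paste0(stem, ".json")
  tr <- RNifti::pixdim(img)[4]
  meta <- list()
  if (file.exists(side)) {
    js <- jsonlite::read_json(side)
    tr <- js$RepetitionTime %||% tr
    meta <- js
  }
  if (!is.null(expectTr) && abs(tr - expectTr) > 1e-6)
    stop(sprintf("TR mismatch: sidecar says %.4f s, config expects %.4f s",
                 tr, expectTr))
  if (is.null(mask)) mask <- apply(dat != 0, 1:3, any)
  mo <- paste0(stem, "_motion.tsv")
  if (file.exists(mo)) meta$motion <- as.matrix(readMotion(mo))
  new("BoldRun", data = dat, tr = as.numeric(tr), mask = mask,
      affine = diag(c(RNifti::pixdim(img)[1:3], 1)), meta = meta)
}

#' Write/read paradigm event tables (BIDS-flavoured TSV)
#'
#' Columns \code{onset}, \code{duration}, \code{trial_type} and, for event
#' tasks, \code{correct}.
#'
#' @param paradigm a \linkS4class{ParadigmSpec}.
#' @param path TSV file.
#' @return \code{writeEvents}: the path, invisibly. \code{readEvents}: a
#'   data.frame; a missing \code{onset}/\code{duration}/\code{trial_type}
#'   column is a schema error naming the column.
#' @export
writeEvents <- function(paradigm, path) {
  df <- data.frame(onset = paradigm@onsets, duration = paradigm@durations,
                   trial_type = paradigm@conditions)
  if (length(paradigm@correctness))
    df$correct <- as.integer(paradigm@correctness)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("missing events file: ", path)
  df <- utils::read.delim(path)
  for (col in c("onset", "duration", "trial_type"))
    if (!col %in% names(df))
      stop(sprintf("events file %s lacks required column '%s'", path, col))
  df
}

#' Write/read a physiological CO2 trace (TSV: time, co2_mmHg)
#'
#' @param trace a \linkS4class{RespiratoryTrace}.
#' @param path TSV file.
#' @return \code{writePhysio}: the path. \code{readPhysio}: a
#'   \linkS4class{RespiratoryTrace}; non-uniform sampling is resampled to
#'   the median step with a warning.
#' @export
writePhysio <- function(trace, path) {
  utils::write.table(data.frame(time = trace@time, co2_mmHg = trace@co2),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhysio
#' @param breathPeriod breath period recorded on the returned object (s).
#' @export
readPhysio <- function(path, breathPeriod = 4) {
  if (!file.exists(path)) stop("missing physio file: ", path)
  df <- utils::read.delim(path)
  for (col in c("time", "co2_mmHg"))
    if (!col %in% names(df))
      stop(sprintf("physio file %s lacks required column '%s'", path, col))
  dt <- diff(df$time)
  if (diff(range(dt)) > 1e-6) {
    warning("non-uniform physio sampling; resampling to the median step")
    step <- stats::median(dt)
    tt <- seq(min(df$time), max(df$time), by = step)
    co2 <- stats::approx(df$time, df$co2_mmHg, xout = tt)$y
    df <- data.frame(time = tt, co2_mmHg = co2)
  }
  new("RespiratoryTrace", time = df$time, co2 = df$co2_mmHg,
      breathPeriod = breathPeriod)
}

#' Read a 6-column motion-parameter table
#'
#' @param path TSV with 6 unlabelled columns.
#' @return data.frame of 6 numeric columns.
#' @export
readMotion <- function(path) {
  if (!file.exists(path)) stop("missing motion file: ", path)
  df <- utils::read.delim(path, header = FALSE)
  if (ncol(df) != 6) stop("motion file must have exactly 6 columns")
  df
}

#' Write a statistic or PSC map as NIfTI with a JSON sidecar
#'
#' @param map a \linkS4class{StatMap}, \linkS4class{PscMap} or
#'   \linkS4class{CvrMap}.
#' @param path file stem; writes \code{<stem>.nii} (+\code{_p.nii} for
#'   statistic maps) and \code{<stem>.json}.
#' @param extra named list merged into the sidecar.
#' @return files written, invisibly.
#' @export
writeMap <- function(map, path, extra = list()) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  files <- character(0)
  side <- list()
  if (is(map, "StatMap")) {
    RNifti::writeNifti(RNifti::asNifti(nafill0(map@t)), paste0(stem, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(nafill0(map@p, 1)),
                       paste0(stem, "_p.nii"))
    files <- c(paste0(stem, ".nii"), paste0(stem, "_p.nii"))
    side <- list(type = "t", dof = map@dof, contrast = map@contrast)
  } else if (is(map, "PscMap")) {
    RNifti::writeNifti(RNifti::asNifti(nafill0(map@psc)),
                       paste0(stem, ".nii"))
    files <- paste0(stem, ".nii")
    side <- list(type = "psc", units = "%")
  } else if (is(map, "CvrMap")) {
    RNifti::writeNifti(RNifti::asNifti(nafill0(map@cvr)),
                       paste0(stem, ".nii"))
    files <- paste0(stem, ".nii")
    side <- list(type = "cvr", units = map@units,
                 max_change_mmHg = map@maxChange)
  } else stop("unsupported map class")
  jsonlite::write_json(c(side, extra), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, paste0(stem, ".json")))
}

nafill0 <- function(x, fill = 0) { x[is.na(x)] <- fill; x }

#' Write a simulated dataset to disk
#'
#' Emits NIfTI volumes, events TSV, physio TSV, motion TSV and JSON
#' sidecars for a set of simulated runs, plus a manifest listing every
#' file with its MD5 checksum.
#'
#' @param runs named list of \linkS4class{BoldRun}s (names become file
#'   stems).
#' @param outDir output directory (created if needed).
#' @return data.frame manifest (\code{file}, \code{md5}), also written as
#'   \code{manifest.tsv} in \code{outDir}.
#' @export
writeDataset <- function(runs, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stopifnot(length(runs) > 0, !is.null(names(runs)),
            !anyDuplicated(names(runs)))
  files <- character(0)
  for (nm in names(runs)) {
    run <- runs[[nm]]
    stem <- file.path(outDir, nm)
    if (file.exists(paste0(stem, ".nii")))
      stop("name collision: ", paste0(stem, ".nii"))
    files <- c(files, writeBoldRun(run, stem))
    if (!is.null(run@meta$paradigm))
      files <- c(files, writeEvents(run@meta$paradigm,
                                    paste0(stem, "_events.tsv")))
    if (!is.null(run@meta$trace))
      files <- c(files, writePhysio(run@meta$trace,
                                    paste0(stem, "_physio.tsv")))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}
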
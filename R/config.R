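#' @include AllClasses.R
NULL

#' Analysis run configuration
#'
#' A fully serializable bundle of every threshold and grid the pipeline
#' applies, so a saved config re-executes deterministic stages
#' bit-identically. Two presets bundle the two acquisition conventions:
#' \code{mode = "exp1"} (breath-hold CVR: TR 2 s, no smoothing, lag grid
#' 0-12 s in TR steps) and \code{mode = "exp2"} (gas CVR: TR 1.8 s, 4 mm
#' smoothing, shift grid 0-18 s in TR steps).
#'
#' @param mode \code{"exp1"} or \code{"exp2"}.
#' @param ... overrides of individual fields.
#' @return A list of class \code{RunConfig}.
#' @export
runConfig <- function(mode = c("exp1", "exp2"), ...) {
  mode <- match.arg(mode)
  base <- list(
    mode = mode,
    tr = if (mode == "exp1") 2 else 1.8,
    smoothFwhm = if (mode == "exp1") 0 else 4,
    voxelAlpha = 0.001,
    fdrQ = 0.05,
    minN = 10,
    madK = 3,
    madCenter = "mean",
    sdK = 3,
    fallbackThreshold = 100,
    maxLag = 12,
    maxShift = 18,
    drift = "linear",
    highpass = 128,
    nParcels = 68,
    gridShape = c(24, 24, 18),
    couplingSlope = 0.5,
    couplingIntercept = 0.2,
    subjectSd = 0.3,
    cvrLogMean = log(0.2),
    cvrLogSd = 0.25,
    cvrSubjectSd = 0.3,
    deltaPetco2 = 9.81,
    noiseSd = 0.5,
    nSubjects = 10,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  structure(base, class = c("RunConfig", "list"))
}

#' Save / load a configuration (YAML or JSON by extension)
#'
#' @param config a \code{RunConfig}.
#' @param path file ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{saveConfig}: the path, invisibly; \code{loadConfig}: the
#'   \code{RunConfig}.
#' @export
saveConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, c(list(mode = raw$mode),
                       raw[setdiff(names(raw), "mode")]))
}

#' Write a provenance log for a pipeline stage
#'
#' Records the config (and its hash), the seeds and thresholds actually
#' applied, and package/R versions, as JSON next to the stage outputs.
#'
#' @param outDir stage output directory.
#' @param config the \code{RunConfig} used.
#' @param stage stage name.
#' @param applied named list of thresholds/seeds actually applied.
#' @return the log path, invisibly.
#' @export
writeProvenance <- function(outDir, config, stage, applied = list()) {
  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA)
  log <- list(stage = stage,
              config_md5 = unname(tools::md5sum(
                writeTempText(as.character(cfgJson)))),
              config = unclass(config),
              applied = applied,
              r_version = as.character(getRversion()),
              package_version = as.character(
                utils::packageVersion("cvrcoupling")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(outDir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

writeTempText <- function(x) {
  f <- tempfile(fileext = ".json")
  writeLines(x, f)
  f
}
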
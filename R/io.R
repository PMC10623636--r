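#' @include AllClasses.R optical-train.R medium.R dynamics.R camera.R
NULL

#' Read / write an optical configuration file
#'
#' YAML (or JSON) files whose keys mirror the constructor arguments of
#' [opticalTrainConfig()], [mediumParticleConfig()], [simulationRun()] and
#' [cameraOpticsConfig()], grouped under `optics`, `medium`, `run` and
#' `camera` sections. Missing sections fall back to the defaults.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return For `readPipelineConfigFile`, a [pipelineConfig()]-style list.
#' @export
readPipelineConfigFile <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args))
  cfg <- pipelineConfig()
  if (!is.null(raw$optics)) cfg$optics <- build(opticalTrainConfig, raw$optics)
  if (!is.null(raw$medium)) cfg$medium <- build(mediumParticleConfig, raw$medium)
  if (!is.null(raw$run)) cfg$run <- build(simulationRun, raw$run)
  if (!is.null(raw$camera)) cfg$camera <- build(cameraOpticsConfig, raw$camera)
  for (k in c("tracking", "fieldR", "fieldZ", "contourZRange"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  cfg
}

#' Export intensity maps as multipage TIFF
#'
#' One normalized 32-bit page per z plane of the field's intensity, for
#' visual comparison with experimental depth sections.
#'
#' @param field A [FocalField-class].
#' @param path Output TIFF path.
#' @param perPlane Normalize each plane to its own maximum.
#' @return `path`, invisibly.
#' @export
writeIntensityTiff <- function(field, path, perPlane = TRUE) {
  I <- intensityMap(field, perPlane = perPlane)
  pages <- lapply(seq_along(field@z), function(j) {
    m <- matrix(I[, , j], nrow = dim(I)[1])
    m / max(m, 1e-300)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
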
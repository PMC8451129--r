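#' Write/read an image series as NIfTI plus JSON sidecar
#'
#' The 4D volume goes to \code{<prefix>.nii.gz} and the per-frame metadata
#' (inversion/echo times, b-values, directions) to \code{<prefix>.json}.
#'
#' @param series an \linkS4class{ImageSeries}.
#' @param prefix output path prefix (no extension).
#' @return Invisibly, the NIfTI path.
#' @export
writeImageSeriesNifti <- function(series, prefix) {
  path <- paste0(prefix, ".nii.gz")
  pix <- if (is.finite(series@pixelSpacing)) series@pixelSpacing else 1
  dz <- if (length(series@sliceZ) > 1L) diff(series@sliceZ[1:2]) else 1
  img <- RNifti::asNifti(imageData(series), pixdim = c(pix, pix, dz, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(c(as.list(frameMeta(series)),
                         list(kind = series@kind,
                              pixelSpacing = series@pixelSpacing,
                              sliceZ = series@sliceZ)),
                       paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageSeriesNifti
#' @export
readImageSeriesNifti <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  dat <- array(as.numeric(img), dim(img))
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  kind <- side$kind; side$kind <- NULL
  ps <- suppressWarnings(as.numeric(side$pixelSpacing))
  side$pixelSpacing <- NULL
  sz <- suppressWarnings(as.numeric(side$sliceZ))
  side$sliceZ <- NULL
  new("ImageSeries", data = dat, meta = as.data.frame(side),
      pixelSpacing = if (!length(ps)) NA_real_ else ps,
      sliceZ = if (!length(sz)) numeric(dim(dat)[3]) else sz,
      kind = if (is.null(kind)) "unknown" else as.character(kind))
}

#' Write/read diffusion protocols in the FSL bval/bvec text dialect
#'
#' \code{<prefix>.bval} holds one whitespace-separated row of b-values;
#' \code{<prefix>.bvec} holds three rows (x, y, z components).
#'
#' @param protocol a \linkS4class{DiffusionProtocol}.
#' @param prefix output path prefix.
#' @param averages signal averages to attach on read.
#' @return \code{writeBvalBvec} invisibly returns the prefix;
#'   \code{readBvalBvec} returns a \linkS4class{DiffusionProtocol}.
#' @export
writeBvalBvec <- function(protocol, prefix) {
  writeLines(paste(protocol@bval, collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(protocol@bvec), 1, paste, collapse = " "),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname writeBvalBvec
#' @export
readBvalBvec <- function(prefix, averages = 1L) {
  bval <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvec <- matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE),
                 nrow = 3, byrow = TRUE)
  diffusionProtocol(bval, t(bvec), averages = averages)
}

#' Write/read tracked contours as CSV
#'
#' Long format with columns slice, phase, contour, point_id, x_mm, y_mm,
#' z_mm; the initial longitudinal slice positions are recovered from the
#' phase-0 rows on read.
#'
#' @param tc a \linkS4class{TrackedContours}.
#' @param path CSV file path.
#' @return \code{readTrackedContours} returns a
#'   \linkS4class{TrackedContours}.
#' @export
writeTrackedContours <- function(tc, path) {
  write.csv(tc@points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackedContours
#' @export
readTrackedContours <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  p0 <- p[p$phase == min(p$phase) & p$contour != "landmark", ]
  z <- tapply(p0$z_mm, p0$slice, function(v) v[1])
  new("TrackedContours", points = p, sliceZ = as.numeric(z),
      phases = length(unique(p$phase)))
}

#' Read/write a phantom configuration document
#'
#' Single YAML or JSON document holding the arguments of
#' \code{\link{phantomConfig}}; the regional table is stored as a list of
#' per-region records.
#'
#' @param path file path (.yaml/.yml or .json).
#' @param config a \linkS4class{PhantomConfig} to write.
#' @return \code{readPhantomConfigFile} returns a
#'   \linkS4class{PhantomConfig}.
#' @export
readPhantomConfigFile <- function(path) {
  doc <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$regional)) {
    doc$regional <- as.data.frame(doc$regional)
  }
  if (!is.null(doc$strainTargets))
    doc$strainTargets <- unlist(doc$strainTargets)
  do.call(phantomConfig, doc)
}

#' @rdname readPhantomConfigFile
#' @export
writePhantomConfigFile <- function(config, path) {
  doc <- list(
    nSlices = config@nSlices, sliceThickness = config@sliceThickness,
    sliceGap = config@sliceGap, pixelSpacing = config@pixelSpacing,
    gridSize = config@gridSize, endoRadius = config@endoRadius,
    epiRadius = config@epiRadius,
    rvInsertionAngle = config@rvInsertionAngle,
    infarctSector = config@infarctSector,
    infarctSlices = config@infarctSlices, bloodPool = config@bloodPool,
    hematocrit = config@hematocrit, timepoint = config@timepoint,
    regional = config@regional, haEndo = config@haEndo,
    haEpi = config@haEpi, torsionSlope = config@torsionSlope,
    peakContractionFraction = config@peakContractionFraction,
    strainTargets = as.list(config@strainTargets),
    noiseSigma = config@noiseSigma, seed = config@seed)
  if (grepl("[.]ya?ml$", path)) yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write phantom ground truth to disk
#'
#' Label maps and parameter maps as NIfTI volumes plus a JSON document of
#' scalar metadata.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeGroundTruth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(a, name) {
    RNifti::writeNifti(RNifti::asNifti(a * 1),
                       file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(gt@myocardium, "myocardium")
  wr(gt@blood, "blood")
  wr(gt@ahaSegments, "aha_segments")
  wr(gt@roiLabels, "roi_labels")
  for (nm in names(gt@maps)) wr(gt@maps[[nm]], paste0("map_", nm))
  jsonlite::write_json(list(timepoint = gt@config@timepoint,
                            sliceZ = gt@sliceZ,
                            pixelSpacing = gt@config@pixelSpacing,
                            sliceThickness = gt@config@sliceThickness,
                            sliceGap = gt@config@sliceGap,
                            hematocrit = gt@config@hematocrit,
                            seed = gt@config@seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
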
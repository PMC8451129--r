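#' @name accessors
#' @title Accessors for cmrphantom classes
#' @description Slot accessors for the package's S4 containers; use these
#'   rather than \code{@}.
#' @param x an object of the documented class.
#' @param name for \code{truthMap}, the map name (\code{"T1native"},
#'   \code{"T1post"}, \code{"T2"}, \code{"MD"}, \code{"FA"}, \code{"HA"},
#'   \code{"depth"}, \code{"scar"}).
#' @return The slot contents; map accessors return arrays on the phantom
#'   grid with \code{NA} outside the mask.
NULL

## internal: scatter a mask-ordered vector back onto the grid
maskedToArray <- function(mask, values, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "ImageSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))
#' @rdname accessors
#' @export
setMethod("frameMeta", "ImageSeries", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("sliceZ", function(x) standardGeneric("sliceZ"))
#' @rdname accessors
#' @export
setMethod("sliceZ", "ImageSeries", function(x) x@sliceZ)
#' @rdname accessors
#' @export
setMethod("sliceZ", "GroundTruth", function(x) x@sliceZ)
#' @rdname accessors
#' @export
setMethod("sliceZ", "TrackedContours", function(x) x@sliceZ)

#' @rdname accessors
#' @export
setGeneric("myocardium", function(x) standardGeneric("myocardium"))
#' @rdname accessors
#' @export
setMethod("myocardium", "GroundTruth", function(x) x@myocardium)

#' @rdname accessors
#' @export
setGeneric("bloodMask", function(x) standardGeneric("bloodMask"))
#' @rdname accessors
#' @export
setMethod("bloodMask", "GroundTruth", function(x) x@blood)

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setMethod("roiLabels", "GroundTruth", function(x) x@roiLabels)

#' @rdname accessors
#' @export
setGeneric("ahaSegments", function(x) standardGeneric("ahaSegments"))
#' @rdname accessors
#' @export
setMethod("ahaSegments", "GroundTruth", function(x) x@ahaSegments)

#' @rdname accessors
#' @export
setGeneric("truthMap", function(x, name) standardGeneric("truthMap"))
#' @rdname accessors
#' @export
setMethod("truthMap", "GroundTruth", function(x, name) {
  if (!name %in% names(x@maps))
    stop("no ground-truth map called '", name, "'")
  x@maps[[name]]
})

#' @rdname accessors
#' @export
setGeneric("phantomConfigOf", function(x) standardGeneric("phantomConfigOf"))
#' @rdname accessors
#' @export
setMethod("phantomConfigOf", "GroundTruth", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("mdMap", function(x) standardGeneric("mdMap"))
#' @rdname accessors
#' @export
setMethod("mdMap", "TensorField", function(x) maskedToArray(x@mask, x@md))

#' @rdname accessors
#' @export
setGeneric("faMap", function(x) standardGeneric("faMap"))
#' @rdname accessors
#' @export
setMethod("faMap", "TensorField", function(x) maskedToArray(x@mask, x@fa))

#' @rdname accessors
#' @export
setGeneric("tensorElements", function(x) standardGeneric("tensorElements"))
#' @rdname accessors
#' @export
setMethod("tensorElements", "TensorField", function(x) x@d)

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setMethod("eigenValues", "TensorField", function(x) x@evals)

#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setMethod("eigenVectors", "TensorField", function(x) x@evecs)

#' @rdname accessors
#' @export
setGeneric("depthMap", function(x) standardGeneric("depthMap"))
#' @rdname accessors
#' @export
setMethod("depthMap", "LVFrameField",
          function(x) maskedToArray(x@mask, x@depth))
#' @rdname accessors
#' @export
setMethod("depthMap", "GroundTruth", function(x) x@maps$depth)

#' @rdname accessors
#' @export
setGeneric("t1Map", function(x) standardGeneric("t1Map"))
#' @rdname accessors
#' @export
setMethod("t1Map", "T1FitResult", function(x) {
  v <- ifelse(x@valid, x@T1, NA_real_)
  maskedToArray(x@mask, v)
})

#' @rdname accessors
#' @export
setGeneric("ecvValues", function(x) standardGeneric("ecvValues"))
#' @rdname accessors
#' @export
setMethod("ecvValues", "ECVMap", function(x) x@ecv)

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setMethod("contourPoints", "TrackedContours", function(x) x@points)

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig [", object@timepoint, "]\n", sep = "")
  cat("  grid ", paste(object@gridSize, collapse = "x"), " px @ ",
      object@pixelSpacing, " mm, ", object@nSlices, " slices (",
      object@sliceThickness, "+", object@sliceGap, " mm)\n", sep = "")
  cat("  annulus ", paste(signif(range(object@endoRadius), 3), collapse = "-"),
      " to ", paste(signif(range(object@epiRadius), 3), collapse = "-"),
      " mm; infarct sector [",
      paste(signif(object@infarctSector, 4), collapse = ", "),
      "] deg on slices ",
      if (length(object@infarctSlices))
        paste(range(object@infarctSlices), collapse = "-") else "none",
      "\n", sep = "")
  cat("  HA ", object@haEndo, " (endo) to ", object@haEpi,
      " (epi) deg; torsion ", object@torsionSlope,
      " deg/mm; noise sigma ", object@noiseSigma, "; seed ",
      object@seed, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth [", object@config@timepoint, "]: ",
      sum(object@myocardium), " myocardial voxels (",
      sum(object@roiLabels == 2L), " infarct ROI, ",
      sum(object@roiLabels == 1L), " remote ROI) on ",
      paste(dim(object@myocardium), collapse = "x"), " grid\n", sep = "")
  cat("  maps:", paste(names(object@maps), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@data)
  cat("ImageSeries <", object@kind, ">: ", d[4], " frames of ",
      paste(d[1:3], collapse = "x"), " voxels\n", sep = "")
  invisible(NULL)
})

setMethod("show", "DiffusionProtocol", function(object) {
  tb <- table(object@bval)
  cat("DiffusionProtocol: ",
      paste(sprintf("%s dirs @ b=%s", tb, names(tb)), collapse = ", "),
      " s/mm^2; ", object@averages, " averages\n", sep = "")
  invisible(NULL)
})

setMethod("show", "TensorField", function(object) {
  cat("TensorField: ", sum(object@mask), " voxels; median MD ",
      signif(stats::median(object@md, na.rm = TRUE), 4), " mm^2/s, median FA ",
      signif(stats::median(object@fa, na.rm = TRUE), 3), "; ",
      sum(object@flagged), " flagged\n", sep = "")
  invisible(NULL)
})

setMethod("show", "T1FitResult", function(object) {
  cat("T1FitResult: ", sum(object@mask), " voxels, ",
      sum(!object@valid), " invalid; median T1 ",
      signif(stats::median(object@T1[object@valid], na.rm = TRUE), 4),
      " ms\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ECVMap", function(object) {
  v <- object@ecv[is.finite(object@ecv)]
  cat("ECVMap: ", length(v), " voxels, median ECV ",
      signif(stats::median(v), 3), "; Hct ", object@hematocrit, "; ",
      object@nClipped, " clipped\n", sep = "")
  invisible(NULL)
})

setMethod("show", "TrackedContours", function(object) {
  cat("TrackedContours: ", length(object@sliceZ), " slices x ",
      object@phases, " phases; contours: ",
      paste(unique(object@points$contour), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})
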
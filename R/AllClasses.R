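#' @import methods
#' @importFrom stats coef lm optimize pt qt rnorm runif sd t.test cor.test
#'   predict complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Phantom configuration
#'
#' Declarative description of the synthetic short-axis left ventricle at one
#' timepoint: geometry, regional ground-truth parameter values, motion and
#' noise settings. Objects are normally built with
#' \code{\link{phantomConfig}} or \code{\link{defaultPhantomConfig}}.
#'
#' @slot nSlices number of short-axis slices, ordered apex to base.
#' @slot sliceThickness,sliceGap slice thickness and inter-slice gap (mm).
#' @slot pixelSpacing in-plane pixel size (mm).
#' @slot gridSize image matrix size, length-2 integer (pixels).
#' @slot endoRadius,epiRadius endo-/epicardial radii (mm), scalar or one
#'   value per slice (mild apex-base taper).
#' @slot rvInsertionAngle anterior RV-insertion reference angle (degrees),
#'   the zero of the AHA parcellation.
#' @slot infarctSector start/end angle (degrees) of the infarcted sector;
#'   equal angles mean no infarct.
#' @slot infarctSlices slice indices carrying the infarct.
#' @slot bloodPool include cavity (blood) voxels.
#' @slot hematocrit blood hematocrit fraction in (0, 1).
#' @slot timepoint label, one of \code{baseline, day6, week5, week9}.
#' @slot regional data.frame with one row per region (\code{remote},
#'   \code{infarct}, \code{blood}) and columns \code{T1native}, \code{T1post}
#'   (ms), \code{T2} (ms), \code{MD} (10^-3 mm^2/s), \code{FA}, \code{scar}.
#' @slot haEndo,haEpi helix angle at the endo- and epicardial border
#'   (degrees); positive (right-handed) endo, negative (left-handed) epi.
#' @slot torsionSlope prescribed torsion (degrees/mm).
#' @slot peakContractionFraction cardiac-cycle fraction of peak contraction.
#' @slot strainTargets named numeric (GRS, GCS, GLS), percent.
#' @slot noiseSigma noise standard deviation as a fraction of the reference
#'   signal of each simulated acquisition.
#' @slot seed integer RNG seed for all noise in this phantom.
#' @export
setClass("PhantomConfig",
  representation(
    nSlices = "integer",
    sliceThickness = "numeric",
    sliceGap = "numeric",
    pixelSpacing = "numeric",
    gridSize = "integer",
    endoRadius = "numeric",
    epiRadius = "numeric",
    rvInsertionAngle = "numeric",
    infarctSector = "numeric",
    infarctSlices = "integer",
    bloodPool = "logical",
    hematocrit = "numeric",
    timepoint = "character",
    regional = "data.frame",
    haEndo = "numeric",
    haEpi = "numeric",
    torsionSlope = "numeric",
    peakContractionFraction = "numeric",
    strainTargets = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  endo <- rep_len(object@endoRadius, object@nSlices)
  epi <- rep_len(object@epiRadius, object@nSlices)
  if (any(endo >= epi))
    msg <- c(msg, "endoRadius must be < epiRadius on every slice")
  if (object@hematocrit <= 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must lie strictly between 0 and 1")
  reg <- object@regional
  need <- c("region", "T1native", "T1post", "T2", "MD", "FA", "scar")
  if (!all(need %in% names(reg)))
    msg <- c(msg, paste("regional table needs columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(reg$FA < 0 | reg$FA >= 1))
      msg <- c(msg, "regional FA must lie in [0, 1)")
    if (any(reg$MD <= 0))
      msg <- c(msg, "regional MD must be positive")
  }
  if (!(object@haEndo > 0 && object@haEpi < 0))
    msg <- c(msg, "haEndo must be > 0 and haEpi < 0 (right-handed endo, left-handed epi)")
  if (length(object@gridSize) != 2L || any(object@gridSize < 4L))
    msg <- c(msg, "gridSize must be two integers >= 4")
  fov <- min(object@gridSize) * object@pixelSpacing / 2
  if (max(epi) >= fov)
    msg <- c(msg, "grid too small to contain epiRadius")
  if (length(object@infarctSlices) &&
      any(object@infarctSlices < 1L | object@infarctSlices > object@nSlices))
    msg <- c(msg, "infarctSlices out of slice range")
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Voxelwise ground truth for one phantom timepoint: masks, AHA segment
#' labels, region-of-interest labels and true parameter maps.
#'
#' @slot config the generating \linkS4class{PhantomConfig}.
#' @slot myocardium,blood logical arrays (x, y, slice).
#' @slot ahaSegments integer array of AHA ring-scheme segment labels (1-16,
#'   0 outside the myocardium).
#' @slot roiLabels integer array: 0 none, 1 remote (septal), 2 infarct,
#'   3 blood.
#' @slot maps named list of ground-truth arrays: \code{T1native},
#'   \code{T1post}, \code{T2}, \code{MD}, \code{FA}, \code{HA}, \code{depth}
#'   (transmural depth, percent) and logical \code{scar}.
#' @slot sliceZ longitudinal position of each slice (mm, apex = 0).
#' @export
setClass("GroundTruth",
  representation(
    config = "PhantomConfig",
    myocardium = "array",
    blood = "array",
    ahaSegments = "array",
    roiLabels = "array",
    maps = "list",
    sliceZ = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  myo <- object@myocardium
  roi <- object@roiLabels
  if (!identical(dim(myo), dim(roi)))
    msg <- c(msg, "myocardium and roiLabels dimensions differ")
  if (any((roi == 1L | roi == 2L) & !myo))
    msg <- c(msg, "infarct/remote ROIs must lie inside the myocardium")
  ha <- object@maps$HA
  if (!is.null(ha) && any(abs(ha[myo]) > 90 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "HA must lie in [-90, 90] degrees")
  if (length(object@sliceZ) != dim(myo)[3])
    msg <- c(msg, "sliceZ length must equal slice count")
  if (length(msg)) msg else TRUE
})

#' Image series
#'
#' A stack of short-axis volumes with per-frame acquisition metadata: the
#' phantom's stand-in for a NIfTI series plus its JSON sidecar.
#'
#' @slot data 4D numeric array (x, y, slice, frame).
#' @slot meta data.frame with one row per frame; columns depend on the
#'   acquisition (\code{TI} ms for MOLLI, \code{TE} ms for multi-echo,
#'   \code{b} s/mm^2 and \code{gx,gy,gz} for diffusion, \code{phase} for
#'   cine-type series).
#' @slot pixelSpacing in-plane pixel size (mm).
#' @slot sliceZ slice longitudinal positions (mm).
#' @slot kind acquisition label (\code{"dwi"}, \code{"molli"},
#'   \code{"multiecho"}, \code{"lge"}).
#' @export
setClass("ImageSeries",
  representation(
    data = "array",
    meta = "data.frame",
    pixelSpacing = "numeric",
    sliceZ = "numeric",
    kind = "character"
  )
)

setValidity("ImageSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (x, y, slice, frame)")
  if (nrow(object@meta) != d[4])
    return("meta must have one row per frame")
  TRUE
})

#' Diffusion encoding protocol
#'
#' Multi-shell diffusion protocol: b-values, unit gradient directions and
#' the number of signal averages. The default
#' (\code{\link{defaultDiffusionProtocol}}) is the 18-direction scheme with
#' 3 directions at b = 100, 3 at b = 200 and 12 at b = 450 s/mm^2 and
#' 8 averages.
#'
#' @slot bval numeric vector of b-values (s/mm^2).
#' @slot bvec n x 3 matrix of unit gradient directions.
#' @slot averages number of signal averages.
#' @export
setClass("DiffusionProtocol",
  representation(bval = "numeric", bvec = "matrix", averages = "integer")
)

setValidity("DiffusionProtocol", function(object) {
  msg <- character()
  if (ncol(object@bvec) != 3L || nrow(object@bvec) != length(object@bval))
    return("bvec must be an n x 3 matrix matching bval")
  nrm <- sqrt(rowSums(object@bvec^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "gradient directions must be unit vectors")
  if (any(object@bval < 0))
    msg <- c(msg, "b-values must be >= 0")
  uniq <- unique(round(object@bvec, 6))
  if (nrow(uniq) < 6L)
    msg <- c(msg, "need >= 6 unique gradient directions")
  if (length(unique(object@bval)) < 2L)
    msg <- c(msg, "need >= 2 distinct b-shells (ln S0 otherwise unidentifiable)")
  if (object@averages < 1L)
    msg <- c(msg, "averages must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Voxelwise diffusion-tensor field
#'
#' Symmetric 3x3 diffusion tensor per masked voxel together with its
#' eigensystem and the derived mean diffusivity and fractional anisotropy.
#' Per-voxel quantities are stored in mask order (\code{which(mask)}).
#'
#' @slot mask logical array of fitted voxels.
#' @slot d n x 6 matrix of unique tensor elements
#'   (xx, yy, zz, xy, xz, yz), mm^2/s.
#' @slot evals n x 3 eigenvalues, descending.
#' @slot evecs 3 x 3 x n array, columns are the matching eigenvectors.
#' @slot md,fa mean diffusivity (mm^2/s) and fractional anisotropy.
#' @slot flagged logical, voxels where signals were clipped or eigenvalues
#'   went negative under noise.
#' @export
setClass("TensorField",
  representation(
    mask = "array",
    d = "matrix",
    evals = "matrix",
    evecs = "array",
    md = "numeric",
    fa = "numeric",
    flagged = "logical"
  )
)

setValidity("TensorField", function(object) {
  n <- sum(object@mask)
  if (nrow(object@d) != n || nrow(object@evals) != n)
    return("per-voxel rows must match the number of masked voxels")
  if (any(object@fa < -1e-9 | object@fa > 1 + 1e-9, na.rm = TRUE))
    return("FA must lie in [0, 1]")
  TRUE
})

#' Local left-ventricular coordinate frames
#'
#' Per-voxel radial, circumferential and longitudinal unit vectors and the
#' normalized transmural depth (0 percent at the endocardial border,
#' 100 percent at the epicardial border). Vectors are stored in mask order.
#'
#' @slot mask logical array.
#' @slot rhat,chat,lhat n x 3 matrices of unit vectors (radial outward,
#'   circumferential, longitudinal apex-to-base).
#' @slot depth transmural depth per voxel (percent).
#' @export
setClass("LVFrameField",
  representation(
    mask = "array",
    rhat = "matrix",
    chat = "matrix",
    lhat = "matrix",
    depth = "numeric"
  )
)

setValidity("LVFrameField", function(object) {
  n <- sum(object@mask)
  if (nrow(object@rhat) != n || nrow(object@chat) != n ||
      nrow(object@lhat) != n || length(object@depth) != n)
    return("per-voxel rows must match the number of masked voxels")
  dots <- rowSums(object@rhat * object@chat)
  if (any(abs(dots) > 1e-6))
    return("radial and circumferential vectors must be orthogonal")
  TRUE
})

#' Tracked contours
#'
#' Point-correspondent contours tracked over the cardiac cycle, as emitted
#' by the phantom's motion simulator: mid-mural, endocardial and epicardial
#' contours per slice plus long-axis landmark points for longitudinal
#' strain.
#'
#' @slot points data.frame with columns \code{slice}, \code{phase}
#'   (0-based), \code{contour} (\code{"mid"}, \code{"endo"}, \code{"epi"},
#'   \code{"landmark"}), \code{point_id}, \code{x_mm}, \code{y_mm},
#'   \code{z_mm}.
#' @slot sliceZ initial (phase-0) longitudinal position per slice (mm).
#' @slot phases number of cardiac phases.
#' @export
setClass("TrackedContours",
  representation(points = "data.frame", sliceZ = "numeric",
                 phases = "integer")
)

setValidity("TrackedContours", function(object) {
  p <- object@points
  need <- c("slice", "phase", "contour", "point_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(p)))
    return(paste("points needs columns:", paste(need, collapse = ", ")))
  cnt <- tapply(p$point_id, interaction(p$slice, p$contour, drop = TRUE),
                function(id) length(unique(id)))
  byphase <- tapply(seq_len(nrow(p)),
                    interaction(p$slice, p$contour, p$phase, drop = TRUE),
                    length)
  if (length(unique(byphase)) &&
      any(tapply(byphase, sub("[.][0-9]+$", "", names(byphase)),
                 function(x) length(unique(x))) != 1L))
    return("point count must be identical across phases (correspondence)")
  TRUE
})

#' MOLLI T1 fit result
#'
#' Per-voxel three-parameter fit of the inversion-recovery magnitude model
#' |A - B exp(-TI/T1*)| with Look-Locker correction T1 = T1* (B/A - 1).
#' Vectors are stored in mask order.
#'
#' @slot mask logical array of fitted voxels.
#' @slot A,B,T1star,T1 per-voxel parameters (signal, signal, ms, ms).
#' @slot residual per-voxel residual norm (signal units).
#' @slot valid logical, FALSE where the fit failed to converge or returned
#'   non-physical parameters; invalid voxels are excluded from ROI means.
#' @export
setClass("T1FitResult",
  representation(
    mask = "array",
    A = "numeric",
    B = "numeric",
    T1star = "numeric",
    T1 = "numeric",
    residual = "numeric",
    valid = "logical"
  )
)

setValidity("T1FitResult", function(object) {
  ok <- object@valid & is.finite(object@T1)
  if (any(object@T1[ok] <= 0))
    return("converged voxels must have T1 > 0")
  err <- abs(object@T1[ok] - object@T1star[ok] *
               (object@B[ok] / object@A[ok] - 1))
  if (any(err > 1e-6 * pmax(object@T1[ok], 1)))
    return("T1 must equal T1star * (B/A - 1)")
  TRUE
})

#' Extracellular-volume map
#'
#' Voxelwise ECV from pre-/post-contrast relaxation-rate changes scaled by
#' (1 - hematocrit), clipped to [0, 1].
#'
#' @slot ecv numeric array, ECV fraction (NA outside the evaluated mask).
#' @slot hematocrit hematocrit used.
#' @slot bloodT1pre,bloodT1post blood-pool T1 inputs (ms).
#' @slot nClipped number of voxels clipped into [0, 1].
#' @export
setClass("ECVMap",
  representation(
    ecv = "array",
    hematocrit = "numeric",
    bloodT1pre = "numeric",
    bloodT1post = "numeric",
    nClipped = "integer"
  )
)

setValidity("ECVMap", function(object) {
  v <- object@ecv[is.finite(object@ecv)]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    return("ECV must be clipped to [0, 1]")
  TRUE
})
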
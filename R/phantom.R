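## Grid conventions: image axes are in mm via pixelSpacing with the LV axis
## at the grid centre; slices are ordered apex -> base with
## z_s = (s-1) * (sliceThickness + sliceGap). Angles are measured
## counterclockwise from +x in degrees; the AHA parcellation starts at the
## configured anterior RV-insertion angle.

.gridCoords <- function(gridSize, pixelSpacing) {
  x <- (seq_len(gridSize[1]) - (gridSize[1] + 1) / 2) * pixelSpacing
  y <- (seq_len(gridSize[2]) - (gridSize[2] + 1) / 2) * pixelSpacing
  list(x = outer(x, rep(1, gridSize[2])),
       y = outer(rep(1, gridSize[1]), y))
}

.inSector <- function(theta, sector) {
  width <- (sector[2] - sector[1]) %% 360
  if (width == 0) return(rep(FALSE, length(theta)))
  ((theta - sector[1]) %% 360) < width
}

## AHA 16-segment ring scheme: basal third 1-6, mid third 7-12 (60-degree
## sectors from the RV insertion), apical third 13-16 (90-degree sectors
## centred on anterior/septal/inferior/lateral).
.ahaSegment <- function(alpha, third) {
  seg <- integer(length(alpha))
  k6 <- floor((alpha %% 360) / 60)
  k4 <- floor(((alpha + 45) %% 360) / 90)
  seg[third == "basal"] <- 1L + k6[third == "basal"]
  seg[third == "mid"] <- 7L + k6[third == "mid"]
  seg[third == "apical"] <- 13L + k4[third == "apical"]
  seg
}

.sliceThirds <- function(nSlices) {
  nApex <- max(1L, round(nSlices / 3))
  nBase <- max(1L, round(nSlices / 3))
  out <- rep("mid", nSlices)
  out[seq_len(nApex)] <- "apical"
  out[seq(nSlices - nBase + 1L, nSlices)] <- "basal"
  out
}

#' Build the phantom ground truth
#'
#' Rasterises the configured LV annulus onto the image grid and produces all
#' ground-truth maps for one timepoint: myocardial/blood masks, AHA segment
#' labels, infarct/remote ROI labels, relaxometry and diffusion parameter
#' maps, the transmural depth map and the linear transmural helix-angle
#' field running from \code{haEndo} at the endocardial border (depth 0)
#' to \code{haEpi} at the epicardial border (depth 100).
#'
#' Within the infarct sector the regional \code{infarct} values override the
#' \code{remote} values (at baseline the two coincide). The remote ROI is
#' all non-infarcted myocardium; the septal AHA segments 8 and 9 used as
#' the paper-style remote reference are available through
#' \code{\link{ahaSegments}} and are required to be disjoint from the
#' infarct sector.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' gt <- buildPhantom(defaultPhantomConfig("day6", gridSize = c(48L, 48L)))
#' gt
#' @export
buildPhantom <- function(config) {
  validObject(config)
  nz <- config@nSlices
  dims <- c(config@gridSize, nz)
  endo <- rep_len(config@endoRadius, nz)
  epi <- rep_len(config@epiRadius, nz)
  g <- .gridCoords(config@gridSize, config@pixelSpacing)
  r2d <- sqrt(g$x^2 + g$y^2)
  theta2d <- (atan2(g$y, g$x) * 180 / pi) %% 360
  alpha2d <- (theta2d - config@rvInsertionAngle) %% 360

  myo <- array(FALSE, dims); blood <- array(FALSE, dims)
  seg <- array(0L, dims); roi <- array(0L, dims)
  depth <- array(NA_real_, dims)
  thirds <- .sliceThirds(nz)
  sectorVox2d <- .inSector(theta2d, config@infarctSector)
  for (s in seq_len(nz)) {
    m <- r2d >= endo[s] & r2d <= epi[s]
    myo[, , s] <- m
    if (config@bloodPool) blood[, , s] <- r2d < endo[s]
    sl <- array(0L, dim(m))
    sl[m] <- .ahaSegment(alpha2d[m], rep(thirds[s], sum(m)))
    seg[, , s] <- sl
    d <- (r2d - endo[s]) / (epi[s] - endo[s]) * 100
    d[!m] <- NA_real_
    depth[, , s] <- pmin(pmax(d, 0), 100)
    inf <- m & sectorVox2d & (s %in% config@infarctSlices)
    rs <- array(0L, dim(m))
    rs[m] <- 1L; rs[inf] <- 2L
    roi[, , s] <- rs
  }
  roi[blood] <- 3L
  if (any(roi == 2L & (seg == 8L | seg == 9L)))
    stop("infarct sector overlaps the septal AHA segments 8/9 ",
         "(remote reference); adjust infarctSector or rvInsertionAngle")

  reg <- config@regional
  pick <- function(col) {
    out <- array(NA_real_, dims)
    out[myo] <- reg[[col]][match("remote", reg$region)]
    out[roi == 2L] <- reg[[col]][match("infarct", reg$region)]
    if (any(blood)) out[blood] <- reg[[col]][match("blood", reg$region)]
    out
  }
  maps <- list(
    T1native = pick("T1native"), T1post = pick("T1post"),
    T2 = pick("T2"),
    MD = pick("MD") * 1e-3,  # regional table is in 1e-3 mm^2/s
    FA = pick("FA"),
    depth = depth
  )
  ha <- config@haEndo + (config@haEpi - config@haEndo) * depth / 100
  ha[!myo] <- NA_real_
  maps$HA <- ha
  scar <- array(FALSE, dims)
  scarFlag <- reg$scar[match("infarct", reg$region)]
  if (isTRUE(scarFlag)) scar[roi == 2L] <- TRUE
  maps$scar <- scar

  new("GroundTruth", config = config, myocardium = myo, blood = blood,
      ahaSegments = seg, roiLabels = roi, maps = maps,
      sliceZ = (seq_len(nz) - 1) * (config@sliceThickness + config@sliceGap))
}

## analytic LV frames on the phantom grid (radial from the LV axis,
## circumferential = lhat x rhat, longitudinal along +z)
.analyticFrames <- function(gt, mask) {
  cfg <- gt@config
  g <- .gridCoords(cfg@gridSize, cfg@pixelSpacing)
  nz <- cfg@nSlices
  th <- atan2(g$y, g$x)
  thAll <- array(rep(th, nz), dim(mask))
  t <- thAll[mask]
  rhat <- cbind(cos(t), sin(t), 0)
  chat <- cbind(-sin(t), cos(t), 0)
  lhat <- cbind(0, 0, rep(1, length(t)))
  d <- gt@maps$depth[mask]
  d[is.na(d)] <- 50  # blood voxels: depth undefined, irrelevant downstream
  new("LVFrameField", mask = mask, rhat = rhat, chat = chat, lhat = lhat,
      depth = d)
}

#' Analytic LV coordinate frames of a phantom
#'
#' Convenience wrapper returning the exact per-voxel radial,
#' circumferential and longitudinal unit vectors and transmural depth of a
#' phantom over its myocardial mask. For frames estimated from contours use
#' \code{\link{localCoordinateFrame}}.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param includeBlood also cover blood-pool voxels (used when building
#'   tensor fields for DWI simulation).
#' @return An \linkS4class{LVFrameField}.
#' @export
lvFrames <- function(gt, includeBlood = FALSE) {
  mask <- gt@myocardium
  if (includeBlood) mask <- mask | gt@blood
  .analyticFrames(gt, mask)
}

#' Construct the ground-truth diffusion tensor field
#'
#' Builds an axially symmetric tensor per voxel whose primary eigenvector
#' lies in the circumferential-longitudinal surface at the prescribed helix
#' angle, with eigenvalues chosen so that recomputing MD and FA from the
#' tensor returns the prescribed values exactly:
#' \code{lambda1 = MD (1 + 2 delta)}, \code{lambda2 = lambda3 =
#' MD (1 - delta)} with \code{delta = FA / sqrt(3 - 2 FA^2)}.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param includeBlood include blood-pool voxels (isotropic-ish tensors with
#'   the blood region's MD/FA).
#' @return A \linkS4class{TensorField} over the phantom mask.
#' @examples
#' gt <- buildPhantom(defaultPhantomConfig(gridSize = c(48L, 48L)))
#' tf <- makeTensorField(gt)
#' range(tf@md) # equals the configured MD
#' @export
makeTensorField <- function(gt, includeBlood = TRUE) {
  mask <- gt@myocardium
  if (includeBlood) mask <- mask | gt@blood
  fr <- .analyticFrames(gt, mask)
  md <- gt@maps$MD[mask]
  fa <- gt@maps$FA[mask]
  ha <- gt@maps$HA[mask]
  ha[is.na(ha)] <- 0  # blood: orientation irrelevant (near-isotropic)
  if (any(fa >= 1)) stop("FA must be < 1 (lambda2 would be <= 0)")
  delta <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * delta)
  l23 <- md * (1 - delta)
  har <- ha * pi / 180
  e1 <- cos(har) * fr@chat + sin(har) * fr@lhat
  n <- length(md)
  d <- cbind(
    l23 + (l1 - l23) * e1[, 1]^2,
    l23 + (l1 - l23) * e1[, 2]^2,
    l23 + (l1 - l23) * e1[, 3]^2,
    (l1 - l23) * e1[, 1] * e1[, 2],
    (l1 - l23) * e1[, 1] * e1[, 3],
    (l1 - l23) * e1[, 2] * e1[, 3]
  )
  colnames(d) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  e2 <- fr@rhat
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  evecs <- array(0, c(3, 3, n))
  evecs[, 1, ] <- t(e1); evecs[, 2, ] <- t(e2); evecs[, 3, ] <- t(e3)
  new("TensorField", mask = mask, d = d,
      evals = cbind(l1, l23, l23), evecs = evecs,
      md = md, fa = fa, flagged = rep(FALSE, n))
}

.tensorSignal <- function(d, bval, bvec) {
  ## n_vox x n_meas matrix of exp(-b g' D g)
  q <- cbind(bvec[, 1]^2, bvec[, 2]^2, bvec[, 3]^2,
             2 * bvec[, 1] * bvec[, 2], 2 * bvec[, 1] * bvec[, 3],
             2 * bvec[, 2] * bvec[, 3]) * bval
  exp(-d %*% t(q))
}

#' Simulate a diffusion-weighted series
#'
#' Forward-models the diffusion signal \code{s0 exp(-b g' D g)} per voxel
#' and encoding, applies Rician noise per signal average and averages the
#' magnitudes (phantom repetitions are co-registered, so averaging needs no
#' registration step).
#'
#' @param tensors a \linkS4class{TensorField}.
#' @param protocol a \linkS4class{DiffusionProtocol}.
#' @param s0 non-diffusion-weighted signal level.
#' @param noiseSigma absolute Gaussian channel sd; alternatively give
#'   \code{noiseFraction} and the sd is that fraction of the mean noise-free
#'   masked signal of the lowest b-shell.
#' @param noiseFraction see \code{noiseSigma}; default NULL.
#' @param seed RNG seed (one stream across all volumes and averages).
#' @return An \linkS4class{ImageSeries} with per-frame \code{b} and gradient
#'   direction metadata.
#' @export
simulateDWI <- function(tensors, protocol, s0 = 1000, noiseSigma = 0,
                        noiseFraction = NULL, seed = 1L) {
  validObject(protocol)
  mask <- tensors@mask
  sig <- s0 * .tensorSignal(tensors@d, protocol@bval, protocol@bvec)
  if (!is.null(noiseFraction)) {
    low <- protocol@bval == min(protocol@bval)
    noiseSigma <- noiseFraction * mean(sig[, low])
  }
  dims <- c(dim(mask), length(protocol@bval))
  set.seed(seed)
  acc <- array(0, dims)
  for (a in seq_len(protocol@averages)) {
    vol <- array(0, dims)
    for (j in seq_len(dims[4])) {
      fr <- array(0, dim(mask))
      fr[mask] <- sig[, j]
      vol[, , , j] <- if (noiseSigma > 0) riceNoise(fr, noiseSigma) else fr
    }
    acc <- acc + vol
  }
  acc <- acc / protocol@averages
  meta <- data.frame(b = protocol@bval, gx = protocol@bvec[, 1],
                     gy = protocol@bvec[, 2], gz = protocol@bvec[, 3])
  new("ImageSeries", data = acc, meta = meta, pixelSpacing = NA_real_,
      sliceZ = numeric(dims[3]), kind = "dwi")
}

#' Default MOLLI inversion times
#'
#' Representative inversion-time sets for pre-contrast (11 delays) and
#' post-contrast (12 delays) MOLLI acquisitions.
#'
#' @param contrast \code{"pre"} or \code{"post"}.
#' @return Numeric vector of inversion times (ms), sorted.
#' @export
defaultInversionTimes <- function(contrast = c("pre", "post")) {
  contrast <- match.arg(contrast)
  if (contrast == "pre")
    c(120, 200, 280, 1120, 1200, 1280, 2120, 2200, 2280, 3120, 4000)
  else
    c(100, 150, 200, 280, 360, 1100, 1180, 1260, 2100, 2180, 3100, 4000)
}

#' Simulate a MOLLI inversion-recovery series
#'
#' Voxel signal \code{|A - B exp(-TI/T1*)|} with ideal inversion
#' \code{B = 2A} by default, under which the Look-Locker identity
#' \code{T1 = T1* (B/A - 1)} gives \code{T1* = T1}. Gaussian noise is added
#' to the signed signal before the magnitude operation.
#'
#' @param t1Map array of T1 values (ms); NA voxels are background.
#' @param inversionTimes inversion delays (ms), at least 4.
#' @param seed RNG seed.
#' @param noiseSigma absolute Gaussian channel sd (signal units).
#' @param A equilibrium signal.
#' @param inversionEfficiency B/(2A); 1 is a perfect inversion.
#' @return An \linkS4class{ImageSeries} with per-frame \code{TI} metadata.
#' @export
simulateMOLLI <- function(t1Map, inversionTimes = defaultInversionTimes(),
                          seed = 1L, noiseSigma = 0, A = 1000,
                          inversionEfficiency = 1) {
  if (length(inversionTimes) < 4L)
    stop("need at least 4 inversion times (fit unidentifiable otherwise)")
  B <- 2 * A * inversionEfficiency
  t1star <- t1Map / (B / A - 1)
  dims <- c(dim(t1Map), length(inversionTimes))
  set.seed(seed)
  out <- array(0, dims)
  for (j in seq_along(inversionTimes)) {
    s <- A - B * exp(-inversionTimes[j] / t1star)
    s[is.na(s)] <- 0
    if (noiseSigma > 0)
      s <- s + rnorm(length(s), 0, noiseSigma)
    out[, , , j] <- abs(s)
  }
  new("ImageSeries", data = out,
      meta = data.frame(TI = inversionTimes),
      pixelSpacing = NA_real_, sliceZ = numeric(dims[3]), kind = "molli")
}

#' Simulate a multi-echo T2 series
#'
#' Voxel signal \code{S0 exp(-TE/T2)} plus Rician noise; the default echo
#' train is 9 echoes with an echo spacing of 8.8 ms.
#'
#' @param t2Map array of T2 values (ms); NA voxels are background.
#' @param echoTimes echo times (ms), all positive.
#' @param seed RNG seed.
#' @param noiseSigma absolute Gaussian channel sd.
#' @param s0 signal at TE = 0.
#' @return An \linkS4class{ImageSeries} with per-frame \code{TE} metadata.
#' @export
simulateMultiEcho <- function(t2Map, echoTimes = 8.8 * (1:9), seed = 1L,
                              noiseSigma = 0, s0 = 1000) {
  if (any(echoTimes <= 0)) stop("echo times must be positive")
  dims <- c(dim(t2Map), length(echoTimes))
  set.seed(seed)
  out <- array(0, dims)
  for (j in seq_along(echoTimes)) {
    s <- s0 * exp(-echoTimes[j] / t2Map)
    s[is.na(s)] <- 0
    out[, , , j] <- if (noiseSigma > 0) riceNoise(s, noiseSigma) else s
  }
  new("ImageSeries", data = out, meta = data.frame(TE = echoTimes),
      pixelSpacing = NA_real_, sliceZ = numeric(dims[3]), kind = "multiecho")
}

#' Simulate a late gadolinium enhancement volume
#'
#' Inversion-nulled remote myocardium with retained contrast in scar:
#' remote voxels draw from Normal(remoteMean, remoteSD), scar voxels from
#' Normal(remoteMean + scarContrast * remoteSD, remoteSD); blood pool and
#' background get distinct means.
#'
#' @param gt a \linkS4class{GroundTruth} whose \code{scar} map marks
#'   enhanced voxels.
#' @param remoteMean,remoteSD remote-myocardium intensity distribution.
#' @param scarContrast scar enhancement in remote-SD units (15 by default,
#'   comfortably above the 5SD segmentation threshold).
#' @param seed RNG seed.
#' @param bloodMean,backgroundMean means for cavity and background voxels.
#' @return A single-frame \linkS4class{ImageSeries} of kind \code{"lge"}.
#' @export
simulateLGE <- function(gt, remoteMean = 100, remoteSD = 10,
                        scarContrast = 15, seed = 1L,
                        bloodMean = remoteMean + 10 * remoteSD,
                        backgroundMean = remoteMean - 5 * remoteSD) {
  if (remoteSD <= 0) stop("remoteSD must be positive")
  set.seed(seed)
  dims <- dim(gt@myocardium)
  img <- array(rnorm(prod(dims), backgroundMean, remoteSD), dims)
  nMyo <- sum(gt@myocardium)
  img[gt@myocardium] <- rnorm(nMyo, remoteMean, remoteSD)
  scar <- gt@maps$scar
  img[scar] <- rnorm(sum(scar), remoteMean + scarContrast * remoteSD,
                     remoteSD)
  if (any(gt@blood))
    img[gt@blood] <- rnorm(sum(gt@blood), bloodMean, remoteSD)
  new("ImageSeries", data = array(img, c(dims, 1L)),
      meta = data.frame(frame = 1L),
      pixelSpacing = gt@config@pixelSpacing, sliceZ = gt@sliceZ,
      kind = "lge")
}

## smooth 0 -> 1 -> 0 contraction activation over `phases` cardiac phases,
## peaking at fraction `peak` of the cycle
.activation <- function(phases, peak) {
  t <- seq_len(phases) - 1
  tp <- max(1L, round(peak * (phases - 1)))
  w <- numeric(phases)
  up <- t <= tp
  w[up] <- sin(pi / 2 * t[up] / tp)^2
  if (tp < phases - 1)
    w[!up] <- sin(pi / 2 * (phases - 1 - t[!up]) / (phases - 1 - tp))^2
  w
}

#' Simulate tracked contour motion
#'
#' Emits point-correspondent mid-mural, endocardial and epicardial contours
#' per slice and phase plus long-axis landmark points. Slice s rotates by
#' \code{torsionSlope * z_s * w(t)} degrees (counterclockwise positive
#' viewed from the apex), where \code{w} is a smooth 0-1-0 activation
#' peaking at the configured contraction fraction; the prescribed global
#' strains scale the mid-wall radius (GCS), wall thickness (GRS) and
#' long-axis length (GLS) by their peak values.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param torsionSlope torsion in degrees/mm (default: the phantom config).
#' @param strainParams named numeric GRS/GCS/GLS targets in percent
#'   (default: the phantom config).
#' @param phases number of cardiac phases (default 26).
#' @param nPoints contour points per slice.
#' @return A \linkS4class{TrackedContours}.
#' @export
simulateContourMotion <- function(gt, torsionSlope = NULL,
                                  strainParams = NULL, phases = 26L,
                                  nPoints = 72L) {
  if (phases < 2L) stop("need at least 2 cardiac phases")
  cfg <- gt@config
  if (is.null(torsionSlope)) torsionSlope <- cfg@torsionSlope
  if (is.null(strainParams)) strainParams <- cfg@strainTargets
  grs <- strainParams[["GRS"]]; gcs <- strainParams[["GCS"]]
  gls <- strainParams[["GLS"]]
  w <- .activation(phases, cfg@peakContractionFraction)
  nz <- cfg@nSlices
  endo0 <- rep_len(cfg@endoRadius, nz)
  epi0 <- rep_len(cfg@epiRadius, nz)
  z0 <- gt@sliceZ
  L0 <- max(z0) + cfg@sliceThickness  # apex-to-base myocardial length
  phi <- 2 * pi * (seq_len(nPoints) - 1) / nPoints
  rows <- vector("list", phases * nz + phases)
  k <- 0L
  for (t in seq_len(phases)) {
    wt <- w[t]
    rot <- torsionSlope * z0 * wt * pi / 180
    zt <- z0 * (1 + gls / 100 * wt)
    for (s in seq_len(nz)) {
      m0 <- (endo0[s] + epi0[s]) / 2
      W0 <- epi0[s] - endo0[s]
      mt <- m0 * (1 + gcs / 100 * wt)
      Wt <- W0 * (1 + grs / 100 * wt)
      radii <- c(mid = mt, endo = mt - Wt / 2, epi = mt + Wt / 2)
      ang <- phi + rot[s]
      k <- k + 1L
      rows[[k]] <- data.frame(
        slice = s, phase = t - 1L,
        contour = rep(names(radii), each = nPoints),
        point_id = rep(seq_len(nPoints), 3L),
        x_mm = as.vector(outer(cos(ang), radii)),
        y_mm = as.vector(outer(sin(ang), radii)),
        z_mm = zt[s])
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      slice = 0L, phase = t - 1L, contour = "landmark",
      point_id = 1:2, x_mm = 0, y_mm = 0,
      z_mm = c(0, L0 * (1 + gls / 100 * wt)))
  }
  new("TrackedContours", points = do.call(rbind, rows[seq_len(k)]),
      sliceZ = z0, phases = as.integer(phases))
}

#' Simulate cavity masks over the cardiac cycle
#'
#' Rasterises the endocardial contour of the moving phantom at each phase,
#' yielding the per-phase LV cavity masks consumed by
#' \code{\link{lvVolumes}}.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param phases number of cardiac phases.
#' @param strainParams named GRS/GCS/GLS targets (default: config).
#' @return List of logical arrays, one per phase.
#' @export
simulateCavityMasks <- function(gt, phases = 26L, strainParams = NULL) {
  cfg <- gt@config
  if (is.null(strainParams)) strainParams <- cfg@strainTargets
  grs <- strainParams[["GRS"]]; gcs <- strainParams[["GCS"]]
  w <- .activation(phases, cfg@peakContractionFraction)
  nz <- cfg@nSlices
  endo0 <- rep_len(cfg@endoRadius, nz)
  epi0 <- rep_len(cfg@epiRadius, nz)
  g <- .gridCoords(cfg@gridSize, cfg@pixelSpacing)
  r2d <- sqrt(g$x^2 + g$y^2)
  lapply(seq_len(phases), function(t) {
    out <- array(FALSE, c(cfg@gridSize, nz))
    for (s in seq_len(nz)) {
      m0 <- (endo0[s] + epi0[s]) / 2
      W0 <- epi0[s] - endo0[s]
      endoT <- m0 * (1 + gcs / 100 * w[t]) - W0 * (1 + grs / 100 * w[t]) / 2
      out[, , s] <- r2d < endoT
    }
    out
  })
}
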
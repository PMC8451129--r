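#' Construct a diffusion protocol
#'
#' @param bval numeric b-values (s/mm^2), one per direction.
#' @param bvec n x 3 matrix of gradient directions (normalised if
#'   \code{normalize = TRUE}, otherwise they must already be unit vectors).
#' @param averages number of signal averages.
#' @param normalize normalise direction rows to unit length.
#' @return A validated \linkS4class{DiffusionProtocol}.
#' @export
diffusionProtocol <- function(bval, bvec, averages = 1L,
                              normalize = FALSE) {
  bvec <- as.matrix(bvec)
  if (normalize) bvec <- bvec / sqrt(rowSums(bvec^2))
  new("DiffusionProtocol", bval = as.numeric(bval), bvec = bvec,
      averages = as.integer(averages))
}

## 12 well-spread unit directions (spherical Fibonacci spiral on the upper
## hemisphere); deterministic, no two collinear
.fibDirections <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default multi-shell diffusion protocol
#'
#' The 18-direction in-vivo cardiac scheme: 3 directions at b = 100,
#' 3 directions at b = 200 and 12 directions at b = 450 s/mm^2, with
#' 8 signal averages. No b = 0 volume is acquired; ln S0 is an unknown of
#' the tensor fit.
#'
#' @param averages number of signal averages (default 8).
#' @return A \linkS4class{DiffusionProtocol}.
#' @export
defaultDiffusionProtocol <- function(averages = 8L) {
  d100 <- diag(3)
  d200 <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, byrow = TRUE) / sqrt(2)
  d450 <- .fibDirections(12L)
  diffusionProtocol(c(rep(100, 3), rep(200, 3), rep(450, 12)),
                    rbind(d100, d200, d450), averages = averages)
}

.designMatrix <- function(protocol) {
  b <- protocol@bval; g <- protocol@bvec
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

.mdFaFromEvals <- function(evals) {
  md <- rowMeans(evals)
  num <- (evals[, 1] - evals[, 2])^2 + (evals[, 2] - evals[, 3])^2 +
    (evals[, 3] - evals[, 1])^2
  den <- rowSums(evals^2)
  fa <- sqrt(0.5) * sqrt(num / den)
  # numerically-zero tensors (|lambda| far below any tissue diffusivity):
  # FA defined as 0, not NaN or noise
  fa[den <= 1e-24] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  list(md = md, fa = fa)
}

#' Fit the diffusion tensor
#'
#' Per-voxel weighted linear least squares on the log signal, solving for
#' \code{[ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]} with weights equal to the
#' squared signal. Signals at or below \code{epsilon} are clipped to
#' \code{epsilon} and the voxel flagged. The eigensystem is computed with
#' eigenvalues in descending order. The protocol design must be full rank;
#' rank deficiency is an error at protocol validation, not per voxel.
#'
#' @param dwi \linkS4class{ImageSeries} whose frames match the protocol
#'   rows in order.
#' @param protocol a \linkS4class{DiffusionProtocol}.
#' @param mask logical array of voxels to fit.
#' @param epsilon positive clipping floor for the log transform.
#' @return A \linkS4class{TensorField}.
#' @export
fitDiffusionTensor <- function(dwi, protocol, mask, epsilon = 1e-6) {
  validObject(protocol)
  X <- .designMatrix(protocol)
  if (qr(X)$rank < 7L)
    stop("rank-deficient diffusion design: directions/shells do not ",
         "identify ln S0 plus the 6 tensor elements")
  dat <- imageData(dwi)
  if (dim(dat)[4] != nrow(X))
    stop("dwi volume count does not match the protocol")
  n <- sum(mask)
  Y <- matrix(sapply(seq_len(nrow(X)), function(j) dat[, , , j][mask]),
              nrow = n)
  flagged <- rowSums(Y <= epsilon) > 0
  Y[Y <= epsilon] <- epsilon
  ly <- log(Y)
  d <- matrix(NA_real_, n, 6,
              dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  evals <- matrix(NA_real_, n, 3)
  evecs <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    w <- Y[i, ]^2
    Xw <- X * w
    beta <- solve(crossprod(Xw, X), crossprod(Xw, ly[i, ]))
    d[i, ] <- beta[2:7]
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    es <- eigen(D, symmetric = TRUE)
    evals[i, ] <- es$values
    evecs[, , i] <- es$vectors
  }
  m <- .mdFaFromEvals(evals)
  flagged <- flagged | evals[, 3] < 0
  new("TensorField", mask = mask, d = d, evals = evals, evecs = evecs,
      md = m$md, fa = m$fa, flagged = flagged)
}

#' Mean diffusivity and fractional anisotropy maps
#'
#' \code{MD = trace/3} and
#' \code{FA = sqrt(1/2) sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)} from the eigensystem; FA of an all-zero tensor
#' is defined as 0 and noisy values are clipped to [0, 1].
#'
#' @param tf a \linkS4class{TensorField}.
#' @return List with arrays \code{md} (mm^2/s) and \code{fa}.
#' @export
tensorMetrics <- function(tf) {
  m <- .mdFaFromEvals(tf@evals)
  list(md = maskedToArray(tf@mask, m$md),
       fa = maskedToArray(tf@mask, m$fa))
}

.contourPolar <- function(contour, centroid) {
  v <- sweep(as.matrix(contour[, 1:2]), 2, centroid)
  a <- atan2(v[, 2], v[, 1])
  r <- sqrt(rowSums(v^2))
  o <- order(a)
  a <- a[o]; r <- r[o]
  gaps <- diff(c(a, a[1] + 2 * pi))
  if (max(gaps) > pi / 2)
    stop("open contour: points do not close around the centroid")
  ## periodic extension for interpolation across the wrap
  list(a = c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi),
       r = c(r[length(r)], r, r[1]))
}

#' Local LV coordinate frames from contours
#'
#' Builds per-voxel radial/circumferential/longitudinal unit vectors and
#' the normalized transmural depth from closed endo- and epicardial
#' contours: the radial direction points outward along the centroid ray,
#' the longitudinal direction is the slice normal (apex to base positive),
#' the circumferential direction completes the right-handed triad, and the
#' depth is the voxel's normalized position on its radial ray between the
#' endocardial (0) and epicardial (100 percent) border.
#'
#' @param mask logical (x, y, slice) array of voxels to cover.
#' @param contours list with one element per slice, each a list with
#'   \code{endo} and \code{epi} matrices of (x_mm, y_mm) points forming a
#'   closed contour.
#' @param pixelSpacing in-plane pixel size (mm).
#' @return An \linkS4class{LVFrameField}.
#' @export
localCoordinateFrame <- function(mask, contours, pixelSpacing) {
  d <- dim(mask)
  if (length(contours) != d[3])
    stop("need one contour set per slice")
  g <- .gridCoords(d[1:2], pixelSpacing)
  rhat <- chat <- lhat <- matrix(NA_real_, sum(mask), 3)
  depth <- numeric(sum(mask))
  off <- 0L
  for (s in seq_len(d[3])) {
    m <- mask[, , s]
    nv <- sum(m)
    if (!nv) next
    cs <- contours[[s]]
    cen <- colMeans(as.matrix(cs$endo[, 1:2]))
    pe <- .contourPolar(cs$endo, cen)
    pp <- .contourPolar(cs$epi, cen)
    vx <- g$x[m] - cen[1]; vy <- g$y[m] - cen[2]
    r <- sqrt(vx^2 + vy^2)
    a <- atan2(vy, vx)
    ct <- ifelse(r > 0, vx / r, 1)
    st <- ifelse(r > 0, vy / r, 0)
    re <- stats::approx(pe$a, pe$r, xout = a)$y
    rp <- stats::approx(pp$a, pp$r, xout = a)$y
    idx <- off + seq_len(nv)
    rhat[idx, ] <- cbind(ct, st, rep(0, nv))
    chat[idx, ] <- cbind(-st, ct, rep(0, nv))
    lhat[idx, ] <- cbind(rep(0, nv), rep(0, nv), rep(1, nv))
    depth[idx] <- pmin(pmax((r - re) / (rp - re) * 100, 0), 100)
    off <- off + nv
  }
  new("LVFrameField", mask = mask, rhat = rhat, chat = chat, lhat = lhat,
      depth = depth)
}

#' Helix-angle map
#'
#' Projects the tensor's primary eigenvector onto the
#' circumferential-longitudinal surface, \code{p = e1 - (e1.rhat) rhat},
#' and returns the angle between the projection and the local
#' circumferential direction, \code{HA = atan2(p.lhat, p.chat)}, mapped to
#' [-90, 90] degrees by the eigenvector sign convention: e1 is flipped so
#' that \code{p.chat >= 0}, and on the boundary (\code{p.chat} about 0) so
#' that \code{p.lhat >= 0}, keeping the map continuous at +/-90. Voxels
#' whose primary eigenvector is dominantly radial
#' (\code{||p|| < radialCutoff}) are masked invalid.
#'
#' @param tf a \linkS4class{TensorField}.
#' @param frames an \linkS4class{LVFrameField} in the same coordinates.
#' @param radialCutoff projection-norm threshold below which a voxel is
#'   discarded as radially oriented.
#' @return Numeric array of helix angles in degrees (NA outside the common
#'   mask and at invalid voxels).
#' @export
helixAngleMap <- function(tf, frames, radialCutoff = 0.2) {
  common <- tf@mask & frames@mask
  it <- match(which(common), which(tf@mask))
  jf <- match(which(common), which(frames@mask))
  e1 <- t(tf@evecs[, 1, it])
  nrm <- sqrt(rowSums(e1^2))
  bad0 <- !is.finite(nrm) | nrm == 0
  r <- frames@rhat[jf, , drop = FALSE]
  c_ <- frames@chat[jf, , drop = FALSE]
  l <- frames@lhat[jf, , drop = FALSE]
  p <- e1 - rowSums(e1 * r) * r
  pn <- sqrt(rowSums(p^2))
  pc <- rowSums(p * c_)
  pl <- rowSums(p * l)
  flip <- pc < 0 | (abs(pc) < 1e-12 & pl < 0)
  pc[flip] <- -pc[flip]
  pl[flip] <- -pl[flip]
  ha <- atan2(pl, pc) * 180 / pi
  ha[pn < radialCutoff | bad0] <- NA_real_
  maskedToArray(common, ha)
}

#' Transmural helix-angle gradient
#'
#' Ordinary least-squares regression of the helix angle (degrees) against
#' the transmural depth (percent) over all valid voxels of the selected
#' AHA segments. The remote septal segments 8 and 9 are the default, the
#' wall at the infarct location being too thin for a reliable transmural
#' fit.
#'
#' @param haMap helix-angle array from \code{\link{helixAngleMap}}.
#' @param frames \linkS4class{LVFrameField} supplying the depth map.
#' @param segments integer array of AHA segment labels.
#' @param useSegments segment labels to include (default 8 and 9).
#' @param minVoxels minimum number of valid voxels required.
#' @return List with \code{slope} (degrees/percent), \code{intercept},
#'   \code{r2}, \code{n} and the slope's standard error \code{se}.
#' @export
transmuralHAGradient <- function(haMap, frames, segments,
                                 useSegments = c(8L, 9L),
                                 minVoxels = 20L) {
  dep <- depthMap(frames)
  sel <- array(segments %in% useSegments, dim(segments)) &
    is.finite(haMap) & is.finite(dep)
  n <- sum(sel)
  if (n < minVoxels)
    stop("only ", n, " valid voxels in AHA segment(s) ",
         paste(useSegments, collapse = ","), "; need >= ", minVoxels)
  fit <- lm(ha ~ depth, data = data.frame(ha = haMap[sel],
                                          depth = dep[sel]))
  sm <- suppressWarnings(summary(fit))  # noiseless fields fit perfectly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, n = n, se = sm$coefficients[2, 2])
}
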
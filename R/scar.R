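#' 5SD scar segmentation and infarct mass
#'
#' Thresholds a late-gadolinium-enhancement volume at
#' \code{mean + sdFactor * SD} of the non-enhanced remote tissue signal and
#' reports scar mass as a percentage of total myocardial mass. An optional
#' largest-connected-component refinement (off by default) stands in for
#' the manual refinement of clinical workflows; when enabled it is recorded
#' in the result.
#'
#' @param lge single-frame \linkS4class{ImageSeries} (or 3D array).
#' @param myocardium logical array, the myocardial mask.
#' @param remote logical array, the remote reference ROI (>= 10 voxels,
#'   disjoint from suspected scar). SD estimation is volumetric across the
#'   whole ROI.
#' @param sdFactor threshold in remote-SD units (default 5).
#' @param voxelVolume voxel volume in ml; defaults to
#'   pixelSpacing^2 x slice spacing / 1000 when \code{lge} carries
#'   geometry.
#' @param density myocardial tissue density (g/ml, default 1.05).
#' @param refine keep only the largest 6-connected scar component.
#' @return List of class \code{"ScarResult"}: \code{scarMask},
#'   \code{threshold}, \code{scarMass} and \code{totalMass} (g),
#'   \code{scarFraction} (percent of LV mass), \code{density},
#'   \code{refined}.
#' @export
segmentScar5SD <- function(lge, myocardium, remote, sdFactor = 5,
                           voxelVolume = NULL, density = 1.05,
                           refine = FALSE) {
  img <- if (is(lge, "ImageSeries")) imageData(lge)[, , , 1] else lge
  if (sum(remote) < 10L)
    stop("remote ROI smaller than 10 voxels; SD unreliable")
  if (any(remote & !myocardium))
    stop("remote ROI must lie inside the myocardium")
  mu <- mean(img[remote]); sdev <- sd(img[remote])
  thr <- mu + sdFactor * sdev
  scar <- myocardium & img > thr
  if (refine && any(scar)) scar <- .largestComponent(scar)
  if (is.null(voxelVolume)) {
    if (is(lge, "ImageSeries") && is.finite(lge@pixelSpacing) &&
        length(lge@sliceZ) > 1L)
      voxelVolume <- lge@pixelSpacing^2 * diff(lge@sliceZ[1:2]) / 1000
    else stop("voxelVolume (ml) required when the series has no geometry")
  }
  totalMass <- sum(myocardium) * voxelVolume * density
  scarMass <- sum(scar) * voxelVolume * density
  structure(list(scarMask = scar, threshold = thr, scarMass = scarMass,
                 totalMass = totalMass,
                 scarFraction = 100 * sum(scar) / sum(myocardium),
                 density = density, refined = refine),
            class = "ScarResult")
}

## largest 6-connected component of a logical 3D array (flood fill)
.largestComponent <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask & lab == 0L)
  nb <- function(i) {
    co <- arrayInd(i, d)
    out <- integer(0)
    for (ax in 1:3) for (dl in c(-1L, 1L)) {
      c2 <- co
      c2[, ax] <- c2[, ax] + dl
      ok <- c2[, ax] >= 1L & c2[, ax] <= d[ax]
      if (any(ok))
        out <- c(out, (c2[ok, 3] - 1L) * d[1] * d[2] +
                   (c2[ok, 2] - 1L) * d[1] + c2[ok, 1])
    }
    out
  }
  while (length(idx)) {
    cur <- cur + 1L
    queue <- idx[1]
    lab[queue] <- cur
    while (length(queue)) {
      nxt <- unique(nb(queue))
      nxt <- nxt[mask[nxt] & lab[nxt] == 0L]
      lab[nxt] <- cur
      queue <- nxt
    }
    idx <- which(mask & lab == 0L)
  }
  if (cur == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' @export
print.ScarResult <- function(x, ...) {
  cat("ScarResult: threshold ", signif(x$threshold, 5), "; scar ",
      signif(x$scarMass, 4), " g of ", signif(x$totalMass, 4), " g (",
      signif(x$scarFraction, 4), "% of LV mass)",
      if (x$refined) "; largest-component refined", "\n", sep = "")
  invisible(x)
}
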
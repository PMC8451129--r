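#' LV volumes and ejection fraction
#'
#' Simpson summation of per-slice cavity areas: volume = sum over slices of
#' area x (sliceThickness + sliceGap). The end-diastolic phase is the
#' maximum-volume phase and the end-systolic phase the minimum;
#' SV = LVEDV - LVESV and LVEF = 100 SV / LVEDV.
#'
#' @param cavityMasks list of logical (x, y, slice) arrays, one per phase.
#' @param sliceThickness,sliceGap slice thickness and gap (mm).
#' @param pixelSpacing in-plane pixel size (mm).
#' @return List with \code{LVEDV}, \code{LVESV}, \code{SV} (ml),
#'   \code{LVEF} (percent), the per-phase \code{volumes} and the ED/ES
#'   phase indices.
#' @examples
#' m <- array(TRUE, c(10, 10, 2))
#' lvVolumes(list(m, m), 10, 0, 2)$SV
#' @export
lvVolumes <- function(cavityMasks, sliceThickness, sliceGap = 0,
                      pixelSpacing = 1) {
  vols <- vapply(cavityMasks, function(m) {
    sum(m) * pixelSpacing^2 * (sliceThickness + sliceGap) / 1000
  }, numeric(1))
  if (all(vols == 0)) stop("empty cavity at all phases")
  ed <- which.max(vols); es <- which.min(vols)
  lvedv <- vols[ed]; lvesv <- vols[es]
  sv <- lvedv - lvesv
  list(LVEDV = lvedv, LVESV = lvesv, SV = sv, LVEF = 100 * sv / lvedv,
       volumes = vols, edPhase = ed, esPhase = es)
}

.wrapDeg <- function(a) ((a + 180) %% 360) - 180

## mean rotation (degrees) of a point set about its centroid relative to a
## reference point set with point correspondence
.contourRotation <- function(xy, xy0) {
  cen <- colMeans(xy); cen0 <- colMeans(xy0)
  th <- atan2(xy[, 2] - cen[2], xy[, 1] - cen[1]) * 180 / pi
  th0 <- atan2(xy0[, 2] - cen0[2], xy0[, 1] - cen0[1]) * 180 / pi
  mean(.wrapDeg(th - th0))
}

#' LV torsion from tracked contours
#'
#' Per phase, the rotation of each slice's mid-mural contour about its
#' centroid relative to phase 0 is regressed against the slice's initial
#' longitudinal position; the slope of the line is the torsion (twist per
#' unit length, degrees/mm). The peak is the maximum over phases of the
#' absolute slope, reported at its signed value. Rotation is
#' counterclockwise-positive viewed from the apex.
#'
#' @param tc a \linkS4class{TrackedContours} with a \code{mid} contour on
#'   at least 2 slices at distinct longitudinal positions.
#' @return List with the per-phase \code{torsion} curve (degrees/mm), the
#'   signed \code{peak}, its phase index \code{peakPhase} and the per-phase
#'   per-slice \code{rotation} matrix (degrees).
#' @export
torsionFromContours <- function(tc) {
  p <- tc@points[tc@points$contour == "mid", ]
  slices <- sort(unique(p$slice))
  z <- tc@sliceZ[slices]
  if (length(unique(z)) < 2L)
    stop("all slices share one longitudinal position; slope undefined")
  phases <- sort(unique(p$phase))
  ref <- lapply(slices, function(s) {
    q <- p[p$slice == s & p$phase == phases[1], ]
    as.matrix(q[order(q$point_id), c("x_mm", "y_mm")])
  })
  rot <- matrix(NA_real_, length(phases), length(slices))
  for (ti in seq_along(phases)) {
    for (si in seq_along(slices)) {
      q <- p[p$slice == slices[si] & p$phase == phases[ti], ]
      rot[ti, si] <- .contourRotation(
        as.matrix(q[order(q$point_id), c("x_mm", "y_mm")]), ref[[si]])
    }
  }
  torsion <- apply(rot, 1, function(r) unname(coef(lm(r ~ z))[2]))
  pk <- which.max(abs(torsion))
  list(torsion = torsion, peak = torsion[pk], peakPhase = phases[pk],
       rotation = rot)
}

.perimeter <- function(xy) {
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(rowSums(d^2)))
}

#' Simplified global strains from tracked contours
#'
#' Geometric contour strains between the end-diastolic and end-systolic
#' phases (identified from the mid-wall perimeter): GCS is the relative
#' mid-wall perimeter change averaged over slices, GRS the relative change
#' of the mean wall thickness (endo-to-epi point distance), and GLS the
#' relative change of the long-axis myocardial length taken from the
#' landmark points. These are declared simplifications of
#' feature-tracking strain; see the package vignette.
#'
#' @param tc a \linkS4class{TrackedContours} with \code{endo}, \code{epi}
#'   and \code{mid} contours; landmark points are required for GLS only.
#' @return List with \code{GRS}, \code{GCS}, \code{GLS} (percent; GLS is
#'   \code{NA} with a warning when landmarks are missing) and the ED/ES
#'   phase labels used.
#' @export
globalStrains <- function(tc) {
  p <- tc@points
  phases <- sort(unique(p$phase))
  slices <- sort(unique(p$slice[p$contour == "mid"]))
  perim <- sapply(phases, function(t) {
    mean(vapply(slices, function(s) {
      q <- p[p$slice == s & p$phase == t & p$contour == "mid", ]
      .perimeter(as.matrix(q[order(q$point_id), c("x_mm", "y_mm")]))
    }, numeric(1)))
  })
  ed <- phases[which.max(perim)]; es <- phases[which.min(perim)]
  perSlice <- function(t, fun) {
    vapply(slices, function(s) {
      q <- p[p$slice == s & p$phase == t, ]
      fun(q)
    }, numeric(1))
  }
  gcs <- 100 * mean(perSlice(es, function(q) {
    m <- q[q$contour == "mid", ]
    .perimeter(as.matrix(m[order(m$point_id), c("x_mm", "y_mm")]))
  }) / perSlice(ed, function(q) {
    m <- q[q$contour == "mid", ]
    .perimeter(as.matrix(m[order(m$point_id), c("x_mm", "y_mm")]))
  }) - 1)
  thickness <- function(t) {
    mean(perSlice(t, function(q) {
      en <- q[q$contour == "endo", ]; ep <- q[q$contour == "epi", ]
      en <- en[order(en$point_id), ]; ep <- ep[order(ep$point_id), ]
      mean(sqrt((ep$x_mm - en$x_mm)^2 + (ep$y_mm - en$y_mm)^2))
    }))
  }
  grs <- 100 * (thickness(es) / thickness(ed) - 1)
  lm_ <- p[p$contour == "landmark", ]
  if (nrow(lm_)) {
    axisLen <- function(t) {
      q <- lm_[lm_$phase == t, ]
      q <- q[order(q$point_id), ]
      sqrt(sum((q[2, c("x_mm", "y_mm", "z_mm")] -
                  q[1, c("x_mm", "y_mm", "z_mm")])^2))
    }
    gls <- 100 * (axisLen(es) / axisLen(ed) - 1)
  } else {
    warning("no landmark points: GLS unavailable")
    gls <- NA_real_
  }
  list(GRS = grs, GCS = gcs, GLS = gls, edPhase = ed, esPhase = es)
}
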
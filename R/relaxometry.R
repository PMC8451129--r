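## MOLLI magnitude model: m(TI) = |A - B exp(-TI/T1*)|.
## The fit restores polarity by flipping the sign of the first k samples
## (k near the minimum-magnitude index), solves the then-linear (A, B)
## subproblem in closed form for each candidate T1*, and picks the
## (k, T1*) with the lowest residual: a coarse log-spaced T1* grid shared by
## all voxels (vectorised), then a per-voxel golden-section refinement.

.t1SignedFit <- function(S, TI, t1star) {
  ## S: n x nTI signed signals; returns list(coef n x 2, rss n)
  E <- exp(-TI / t1star)
  X <- cbind(1, -E)
  P <- X %*% solve(crossprod(X))       # nTI x 2
  coefs <- S %*% P
  fit <- tcrossprod(coefs, X)
  list(coef = coefs, rss = rowSums((S - fit)^2))
}

#' Fit a MOLLI T1 map
#'
#' Per-voxel three-parameter least-squares fit of the inversion-recovery
#' magnitude signal \code{|A - B exp(-TI/T1*)|} with polarity restoration
#' (sign hypotheses around the pre-null samples, lower residual wins),
#' followed by the Look-Locker correction \code{T1 = T1* (B/A - 1)}.
#' Initialisation and search are bounded to positive parameters; voxels
#' that do not converge to a physical solution are flagged invalid and
#' excluded from downstream ROI means.
#'
#' @param series \linkS4class{ImageSeries} with \code{TI} metadata
#'   (>= 4 distinct inversion times).
#' @param mask logical array of voxels to fit.
#' @param t1Range search range for apparent T1* (ms).
#' @param gridLength coarse-grid resolution over log T1*.
#' @return A \linkS4class{T1FitResult}.
#' @examples
#' gt <- buildPhantom(defaultPhantomConfig(gridSize = c(48L, 48L),
#'                                         nSlices = 2L))
#' ser <- simulateMOLLI(truthMap(gt, "T1native"))
#' fit <- fitT1Map(ser, myocardium(gt))
#' fit
#' @export
fitT1Map <- function(series, mask, t1Range = c(100, 5000),
                     gridLength = 48L) {
  meta <- frameMeta(series)
  if (is.null(meta$TI)) stop("series carries no inversion-time metadata")
  ord <- order(meta$TI)
  TI <- meta$TI[ord]
  if (length(unique(TI)) < 4L)
    stop("need >= 4 distinct inversion times")
  dat <- imageData(series)
  n <- sum(mask)
  Y <- sapply(ord, function(j) dat[, , , j][mask])
  Y <- matrix(Y, nrow = n)
  nTI <- length(TI)

  imin <- max.col(-Y, ties.method = "first")
  ## second-smallest magnitude index (noise can displace the minimum)
  Y2 <- Y
  Y2[cbind(seq_len(n), imin)] <- Inf
  imin2 <- max.col(-Y2, ties.method = "first")
  ## candidate flip counts per voxel: the null lies adjacent to a
  ## small-magnitude sample, so try flips around the two smallest
  kCand <- cbind(imin - 2L, imin - 1L, imin, imin + 1L,
                 imin2 - 1L, imin2)
  kCand[] <- pmin(pmax(kCand, 0L), nTI)
  grid <- exp(seq(log(t1Range[1]), log(t1Range[2]),
                  length.out = gridLength))
  nSlot <- ncol(kCand)
  slotRss <- matrix(Inf, n, nSlot)
  slotT <- matrix(grid[1], n, nSlot)
  for (k in sort(unique(as.vector(kCand)))) {
    vox <- which(rowSums(kCand == k) > 0)
    if (!length(vox)) next
    S <- Y[vox, , drop = FALSE]
    if (k > 0) S[, seq_len(k)] <- -S[, seq_len(k)]
    for (t1s in grid) {
      f <- .t1SignedFit(S, TI, t1s)
      for (slot in seq_len(nSlot)) {
        sel <- kCand[vox, slot] == k & f$rss < slotRss[vox, slot]
        if (any(sel)) {
          idx <- vox[sel]
          slotRss[idx, slot] <- f$rss[sel]
          slotT[idx, slot] <- t1s
        }
      }
    }
  }

  ## per-voxel refinement of every candidate flip count; the sign
  ## hypothesis with the lowest refined residual wins
  ratio <- (t1Range[2] / t1Range[1])^(1 / (gridLength - 1))
  A <- B <- T1s <- res <- numeric(n)
  for (i in seq_len(n)) {
    bestRss <- Inf; bestFit <- NULL; bestT1s <- NA_real_
    for (slot in which(!duplicated(kCand[i, ]))) {
      k <- kCand[i, slot]
      s <- Y[i, ]
      if (k > 0) s[seq_len(k)] <- -s[seq_len(k)]
      sM <- matrix(s, 1L)
      obj <- function(t1s) .t1SignedFit(sM, TI, t1s)$rss
      lo <- slotT[i, slot] / ratio^1.5
      hi <- slotT[i, slot] * ratio^1.5
      op <- optimize(obj, c(lo, hi), tol = 1e-6)
      if (op$objective < bestRss) {
        bestRss <- op$objective
        bestT1s <- op$minimum
        bestFit <- .t1SignedFit(sM, TI, op$minimum)
      }
    }
    A[i] <- bestFit$coef[1]; B[i] <- bestFit$coef[2]
    T1s[i] <- bestT1s
    res[i] <- sqrt(bestRss)
  }
  T1 <- T1s * (B / A - 1)
  valid <- is.finite(T1) & T1 > 0 & A > 0 & B > 0
  new("T1FitResult", mask = mask, A = A, B = B, T1star = T1s, T1 = T1,
      residual = res, valid = valid)
}

#' Fit a mono-exponential T2 map
#'
#' Per-voxel weighted log-linear least squares of
#' \code{S(TE) = S0 exp(-TE/T2)} with weights equal to the squared signal
#' (down-weighting the noisy tail of the decay); non-positive signals are
#' excluded from the log fit and voxels with fewer than 3 usable echoes are
#' invalid. An optional nonlinear refinement re-minimises the untransformed
#' residual per voxel.
#'
#' @param series \linkS4class{ImageSeries} with \code{TE} metadata
#'   (>= 3 echoes).
#' @param mask logical array of voxels to fit.
#' @param refine logical, run the per-voxel nonlinear refinement.
#' @return Numeric array: the T2 map in ms (NA where invalid), with the
#'   fitted \code{S0} map attached as attribute \code{"s0"}.
#' @export
fitT2Map <- function(series, mask, refine = FALSE) {
  meta <- frameMeta(series)
  if (is.null(meta$TE)) stop("series carries no echo-time metadata")
  TE <- meta$TE
  if (length(TE) < 3L) stop("need >= 3 echoes")
  dat <- imageData(series)
  n <- sum(mask)
  Y <- matrix(sapply(seq_along(TE), function(j) dat[, , , j][mask]),
              nrow = n)
  usable <- Y > 0
  w <- Y^2 * usable
  ly <- log(pmax(Y, .Machine$double.xmin))
  x <- matrix(TE, n, length(TE), byrow = TRUE)
  Sw <- rowSums(w); Swx <- rowSums(w * x); Swy <- rowSums(w * ly)
  Swxx <- rowSums(w * x^2); Swxy <- rowSums(w * x * ly)
  den <- Sw * Swxx - Swx^2
  slope <- (Sw * Swxy - Swx * Swy) / den
  icpt <- (Swy - slope * Swx) / Sw
  t2 <- -1 / slope
  s0 <- exp(icpt)
  bad <- rowSums(usable) < 3L | !is.finite(t2) | t2 <= 0
  if (refine) {
    for (i in which(!bad)) {
      y <- Y[i, ]
      obj <- function(t2v) {
        e <- exp(-TE / t2v)
        s0v <- sum(y * e) / sum(e^2)
        sum((y - s0v * e)^2)
      }
      op <- optimize(obj, c(max(1, t2[i] / 3), t2[i] * 3), tol = 1e-8)
      t2[i] <- op$minimum
      e <- exp(-TE / t2[i])
      s0[i] <- sum(y * e) / sum(e^2)
    }
  }
  t2[bad] <- NA_real_
  out <- maskedToArray(mask, t2)
  attr(out, "s0") <- maskedToArray(mask, ifelse(bad, NA_real_, s0))
  out
}

#' Compute an extracellular-volume map
#'
#' \code{ECV = (1 - Hct) (1/T1post - 1/T1pre) / (1/bloodT1post -
#' 1/bloodT1pre)} per voxel; values outside [0, 1] (possible under noise)
#' are clipped with the clip count recorded rather than failing.
#'
#' @param t1Pre,t1Post arrays of native and post-contrast myocardial T1
#'   (ms); NA voxels are skipped.
#' @param bloodT1pre,bloodT1post blood-pool T1 before/after contrast (ms).
#' @param hematocrit hematocrit fraction in (0, 1).
#' @return An \linkS4class{ECVMap}.
#' @examples
#' ecv <- computeECVMap(array(1000, c(2, 2, 1)), array(400, c(2, 2, 1)),
#'                      1600, 280, hematocrit = 0.45)
#' ecvValues(ecv)[1]
#' @export
computeECVMap <- function(t1Pre, t1Post, bloodT1pre, bloodT1post,
                          hematocrit) {
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie strictly between 0 and 1")
  dR1b <- 1 / bloodT1post - 1 / bloodT1pre
  if (dR1b <= 0)
    stop("blood delta-R1 must be positive (contrast ordering violated)")
  if (any(t1Pre <= 0, na.rm = TRUE) || any(t1Post <= 0, na.rm = TRUE))
    stop("all T1 inputs must be positive")
  ecv <- (1 - hematocrit) * ((1 / t1Post - 1 / t1Pre) / dR1b)
  nClip <- sum(ecv < 0 | ecv > 1, na.rm = TRUE)
  ecv <- pmin(pmax(ecv, 0), 1)
  new("ECVMap", ecv = ecv, hematocrit = hematocrit,
      bloodT1pre = bloodT1pre, bloodT1post = bloodT1post,
      nClipped = as.integer(nClip))
}

#' Integer-pixel translation registration
#'
#' Exhaustive in-plane integer-shift search minimising the sum of squared
#' differences between two volumes, for perturbed inputs; phantom pre/post
#' series are co-registered, so the identity shift is the default pipeline
#' behaviour.
#'
#' @param moving,fixed 3D arrays of identical dimension.
#' @param maxShift maximum |shift| searched per in-plane axis (pixels).
#' @return List with the aligned \code{moving} array and the chosen
#'   \code{shift} (dx, dy).
#' @export
registerTranslation <- function(moving, fixed, maxShift = 3L) {
  stopifnot(identical(dim(moving), dim(fixed)))
  d <- dim(moving)
  shiftArr <- function(a, dx, dy) {
    out <- array(NA_real_, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2])
    xv <- xs - dx; yv <- ys - dy
    okx <- xv >= 1 & xv <= d[1]; oky <- yv >= 1 & yv <= d[2]
    out[xs[okx], ys[oky], ] <- a[xv[okx], yv[oky], ]
    out
  }
  best <- c(0L, 0L); bestSSD <- Inf
  for (dx in -maxShift:maxShift) for (dy in -maxShift:maxShift) {
    sh <- shiftArr(moving, dx, dy)
    ssd <- mean((sh - fixed)^2, na.rm = TRUE)
    if (ssd < bestSSD) { bestSSD <- ssd; best <- c(dx, dy) }
  }
  list(moving = shiftArr(moving, best[1], best[2]), shift = best)
}
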